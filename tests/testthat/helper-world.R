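# A small engineered world shared by scanner and acceptance tests: a
# reference collection with one strongly AuxRE-like planted word (moderate
# occurrence, mid density, TGTCTC-core composition) and one strongly
# non-AuxRE word (very high occurrence, density ~1, AT-rich), plus a
# promoter carrying one copy of each at a distal / core position.
engineeredWorld <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    plants <- rbind(
      do.call(rbind, lapply(1:15, function(p) {
        data.frame(motif = "TTTTATTT", promoter = p, offset = seq(0, 304, by = 16))
      })),
      data.frame(motif = "ATGTCTCA", promoter = c(1:8, 16:22), offset = 500)
    )
    world <- makeMiniCollection(60, 1000, plants, responsive = 1:15, seed = 99)
    set.seed(17)
    prom <- strsplit(paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = ""), "")[[1]]
    prom[293:300] <- strsplit("ATGTCTCA", "")[[1]]  # P = 1000 - 292 = 708 (distal)
    prom[901:908] <- strsplit("TTTTATTT", "")[[1]]  # P = 100 (core)
    cache <<- list(ref = world$collection,
                   promoter = c(drn = paste(prom, collapse = "")))
    cache
  }
})
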
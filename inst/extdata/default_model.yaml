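# Default fusion-model configuration.
#
# Three fuzzified region-mass tables, one per learning graph:
#   score_position     : position from ATG (3 sets) x significance score (4 sets), cells Rij
#   occurrence_density : occurrence (4 sets) x density (3 sets), cells Dij
#   f1_f2              : discriminant scores f1 (4 sets) x f2 (3 sets), cells Qij
# Cell propositions encode the graded doubt P1..P4 assigned to each confidence
# region from the AuxRE / non-AuxRE proportions of the training set.
# Fuzzy sets are trapezoids (a, b, c, d); every partition tiles its axis with
# complementary transition bands so memberships always sum to one.

threshold: 0.9

partitions:
  position:        # bp upstream of the ATG
    - {name: core,     a: -.inf, b: -.inf, c: 200.0, d: 250.0}
    - {name: proximal, a: 200.0, b: 250.0, c: 450.0, d: 550.0}
    - {name: distal,   a: 450.0, b: 550.0, c: .inf,  d: .inf}
  score:           # overrepresentation z-score
    - {name: small,     a: -.inf, b: -.inf, c: 2.0,  d: 5.0}
    - {name: average,   a: 2.0,   b: 5.0,   c: 6.5,  d: 8.0}
    - {name: high,      a: 6.5,   b: 8.0,   c: 14.0, d: 18.0}
    - {name: very_high, a: 14.0,  b: 18.0,  c: .inf, d: .inf}
  occurrence:      # match count over the reference promoter collection
    - {name: small,     a: -.inf, b: -.inf, c: 4.0,   d: 8.0}
    - {name: average,   a: 4.0,   b: 8.0,   c: 38.0,  d: 45.0}
    - {name: high,      a: 38.0,  b: 45.0,  c: 150.0, d: 220.0}
    - {name: very_high, a: 150.0, b: 220.0, c: .inf,  d: .inf}
  density:         # fraction of matches in auxin-responsive promoters
    - {name: small,   a: -.inf, b: -.inf, c: 0.25, d: 0.35}
    - {name: average, a: 0.25,  b: 0.35,  c: 0.65, d: 0.75}
    - {name: high,    a: 0.65,  b: 0.75,  c: .inf, d: .inf}
  f1:              # first discriminant score
    - {name: low,       a: -.inf, b: -.inf, c: -1.10, d: -0.95}
    - {name: mid,       a: -1.10, b: -0.95, c: 0.00,  d: 0.10}
    - {name: high,      a: 0.00,  b: 0.10,  c: 0.45,  d: 0.55}
    - {name: very_high, a: 0.45,  b: 0.55,  c: .inf,  d: .inf}
  f2:              # second discriminant score
    - {name: low,  a: -.inf, b: -.inf, c: -0.15, d: -0.05}
    - {name: mid,  a: -0.15, b: -0.05, c: 0.32,  d: 0.42}
    - {name: high, a: 0.32,  b: 0.42,  c: .inf,  d: .inf}

tables:
  score_position:
    axis1: position
    axis2: score
    # cell labels follow the source table, whose score columns run from the
    # highest score band (j = 1) down to the lowest (j = 4)
    axis2_label_order: descending
    cells:
      R11: P4(H2)
      R12: P2(H2)
      R13: P4(H2)
      R14: P4(H2)
      R21: P4(H1)
      R22: P4(H1)
      R23: P3(H1)
      R24: P4(H2)
      R31: P4(H1)
      R32: P4(H1)
      R33: P4(H1)
      R34: P4(H2)
  occurrence_density:
    axis1: occurrence
    axis2: density
    cells:
      D11: P1
      D12: P3(H2)
      D13: P4(H2)
      D21: P4(H2)
      D22: P3(H1)
      D23: P4(H2)
      D31: P4(H2)
      D32: P4(H2)
      D33: P4(H2)
      D41: P4(H1)
      D42: P4(H2)
      D43: P4(H2)
  f1_f2:
    axis1: f1
    axis2: f2
    cells:
      Q11: P4(H2)
      Q12: P4(H2)
      Q13: P4(H2)
      Q21: P4(H2)
      Q22: P3(H1)
      Q23: P4(H2)
      Q31: P3(H2)
      Q32: P3(H2)
      Q33: P4(H2)
      Q41: P4(H2)
      Q42: P4(H2)
      Q43: P4(H2)

# Reference discriminant axes over (x1, y1, z1, gc). Axis 1 is the base
# composition contrast that carries most of the between-class spread of the
# packaged training set; axis 2 opposes the weak/strong Z-curve component to
# GC fraction.
lda:
  discriminant1: [0.8, 0.6, 0.0, 0.0]
  discriminant2: [0.0, 0.0, 0.9, -0.4358898943540674]
  center: [0.0, 0.0, 0.0, 0.5]
  explained_variance: [0.6, 0.32]
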
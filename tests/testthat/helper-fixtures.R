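# Shared fixtures, built in code at test time.

# Printed two-group anchors (control mean/SD, carrier mean/SD, printed
# posterior effect-size mode and probability-of-difference %), n = 25 each.
tab1_anchor_rows <- function() {
  list(
    t1 = list(mean1 = 273.7, sd1 = 35.1,  mean2 = 266.1, sd2 = 32.3,
              mode = 0.22, pct = 78.3, label = "tonic alertness RT"),
    t2 = list(mean1 = 268.1, sd1 = 33.4,  mean2 = 262.1, sd2 = 32.4,
              mode = 0.19, pct = 76.1, label = "phasic alertness RT"),
    t3 = list(mean1 = 862.7, sd1 = 276.8, mean2 = 744.8, sd2 = 189.8,
              mode = 0.50, pct = 94.8, label = "flexibility RT no hand change"),
    t4 = list(mean1 = 838.5, sd1 = 263.6, mean2 = 733.6, sd2 = 174.6,
              mode = 0.48, pct = 93.8, label = "flexibility overall RT"),
    t5 = list(mean1 = 1.78,  sd1 = 1.20,  mean2 = 1.14,  sd2 = 0.82,
              mode = 0.60, pct = 97.4, label = "verbal learning early recall"),
    t6 = list(mean1 = 1.78,  sd1 = 1.20,  mean2 = 1.14,  sd2 = 0.82,
              mode = 0.60, pct = 97.4, label = "verbal learning early recall"))
}

# moment-matched two-group sample for an anchor row
anchor_groups <- function(row, n = 25, seed = 1) {
  gen_group_scores(group_spec(row$mean1, row$sd1, n, row$mean2, row$sd2, n,
                              moment_match = TRUE, seed = seed))
}

# small orthogonal topography set reused across microstate tests
test_topographies <- function(n_channels = 19, k = 4, seed = 42) {
  random_topographies(n_channels, k, seed = seed)
}
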
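# shared helpers: random covariate draws and small deterministic cohorts

random_infants <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(ga_weeks = runif(n, 24, 30.99),
             sex = sample(1:2, n, replace = TRUE),
             bwsds = runif(n, -4, 2))
}

# tiny cohort with known follow-up structure for expansion tests
toy_cohort <- function() {
  data.frame(id = 1:3,
             ga_weeks = c(24.5, 26, 28 + 3 / 7),
             sex = c(1L, 2L, 1L),
             bwsds = c(-2, 0, 1),
             event = c(1L, 0L, 1L),
             time_weeks = c(10.5, 3.0, 14.0))
}

# brute-force AUC: pairwise concordance with ties counted one half
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
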
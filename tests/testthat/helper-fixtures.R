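# Shared fixture builders. Everything is generated in code at test time.

# samples x genera count matrix with dimnames
toy_counts <- function(n_samples = 6, n_taxa = 4, depth = 100, seed = 1) {
  set.seed(seed)
  m <- t(rmultinom(n_samples, depth, prob = seq_len(n_taxa)))
  dimnames(m) <- list(sprintf("s%02d", seq_len(n_samples)),
                      sprintf("g%02d", seq_len(n_taxa)))
  m
}

# synthetic CLR-like Monte-Carlo array: normal values, optional per-taxon
# case shifts; groups = first n_case samples are cases
normal_clr_array <- function(n_inst = 64, n_case = 30, n_control = 30,
                             n_taxa = 5, shift = numeric(n_taxa), seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  arr <- array(rnorm(n_inst * n * n_taxa), dim = c(n_inst, n, n_taxa),
               dimnames = list(NULL, sprintf("s%03d", seq_len(n)),
                               sprintf("t%02d", seq_len(n_taxa))))
  for (j in seq_len(n_taxa))
    arr[, seq_len(n_case), j] <- arr[, seq_len(n_case), j] + shift[j]
  attr(arr, "groups") <- factor(rep(c("case", "control"),
                                    c(n_case, n_control)),
                                levels = c("control", "case"))
  arr
}

# clean screening roster with optional flagged rows
toy_roster <- function(n = 10, cesd = rep(5, n)) {
  data.frame(
    sample_id = sprintf("p%02d", seq_len(n)), sex = "female",
    japanese = TRUE, pregnant_lactating = FALSE, enema = FALSE,
    antibiotics_3mo = FALSE, questionnaire_response = TRUE,
    depression = FALSE, other_illness = FALSE, cesd = cesd)
}

# small planted cohort config used by pipeline-level tests
small_cohort_config <- function(seed = 1, ...) {
  cohort_config(
    n_case_m = 12L, n_control_m = 48L, n_case_f = 12L, n_control_f = 48L,
    n_taxa = 40L, depth_range = c(2283L, 8000L),
    planted_up = c(genus_003 = 0.6, genus_006 = 0.6),
    planted_down = c(genus_004 = 0.6),
    seed = seed, ...)
}

# brute-force expected richness: average distinct genera over every
# distinct subsample of size n (exhaustive enumeration over read ids)
enum_expected_richness <- function(counts, n) {
  reads <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(reads), n)
  mean(apply(subs, 2, function(ix) length(unique(reads[ix]))))
}
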
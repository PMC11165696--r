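#' Apply cohort exclusion rules to a participant roster
#'
#' Exclusion rules, applied in order: non-Japanese nationality, pregnant
#' or lactating, enema stool, antibiotic intake within 3 months, and
#' non-response to the screening questionnaire. A participant is counted
#' once, under the first rule they fail; a missing flag is treated as
#' non-response.
#'
#' @param roster data.frame with logical columns `japanese`,
#'   `pregnant_lactating`, `enema`, `antibiotics_3mo`,
#'   `questionnaire_response`, plus any metadata columns.
#' @return list with `roster` (screened) and `audit` (class
#'   `screening_audit`): per-rule removal counts in application order,
#'   remaining n, and (when `sex`/`group` columns exist) per-sex
#'   case/control counts.
#' @export
apply_exclusions <- function(roster) {
  flags <- c("japanese", "pregnant_lactating", "enema", "antibiotics_3mo",
             "questionnaire_response")
  missing_cols <- setdiff(flags, names(roster))
  if (length(missing_cols))
    stopf("roster lacks screening flag column(s): %s",
          paste(missing_cols, collapse = ", "))
  n_in <- nrow(roster)
  incomplete <- !complete.cases(roster[flags])
  fails <- cbind(
    non_japanese = !incomplete & !roster$japanese,
    pregnant_lactating = !incomplete & roster$pregnant_lactating,
    enema = !incomplete & roster$enema,
    antibiotics = !incomplete & roster$antibiotics_3mo,
    non_response = incomplete | (!incomplete & !roster$questionnaire_response))
  # first failing rule wins
  first_fail <- apply(fails, 1L, function(r) if (any(r)) which(r)[1] else 0L)
  removed <- first_fail > 0L
  audit_counts <- vapply(seq_len(ncol(fails)),
                         function(j) sum(first_fail == j), integer(1))
  names(audit_counts) <- colnames(fails)
  out <- roster[!removed, , drop = FALSE]
  audit <- structure(list(removed = audit_counts, n_input = n_in,
                          n_remaining = nrow(out)),
                     class = "screening_audit")
  stopifnot(sum(audit_counts) == n_in - nrow(out))
  list(roster = out, audit = audit)
}

#' Assign depression / control groups after screening
#'
#' The depression group is self-reported physician-diagnosed depression.
#' Controls have no current illness or treatment and a CES-D score
#' strictly below 16 (CES-D >= 16 flags suspicion of depression, so such
#' participants are neither case nor control). Everyone else is
#' `unassigned`.
#'
#' @param roster screened data.frame with columns `depression` (logical),
#'   `other_illness` (logical), `cesd` (0-60), `sex`, `sample_id`, and
#'   optionally `age`, `bmi`.
#' @return data.frame of sample metadata with a `group` factor
#'   (`depression`, `control`, `unassigned`).
#' @export
assign_groups <- function(roster) {
  stopifnot(all(c("depression", "other_illness", "cesd") %in% names(roster)))
  if (any(roster$cesd < 0 | roster$cesd > 60, na.rm = TRUE))
    stopf("CES-D scores must lie in [0, 60]")
  group <- ifelse(roster$depression, "depression",
                  ifelse(!roster$other_illness & roster$cesd < 16,
                         "control", "unassigned"))
  out <- roster
  out$group <- factor(group, levels = c("depression", "control", "unassigned"))
  out
}

#' Demographic comparison table (mean +/- SD and p-values), per sex
#'
#' Age and BMI are compared between the depression and control groups by
#' Welch's unequal-variance t-test; CES-D by the two-sided Wilcoxon
#' rank-sum test (exact for small tie-free samples, otherwise the normal
#' approximation with continuity and tie correction, as
#' [stats::wilcox.test()] chooses).
#'
#' @param meta metadata data.frame from [assign_groups()] with columns
#'   `sex`, `group`, `age`, `bmi`, `cesd`.
#' @return data.frame: one row per sex x variable with group means, SDs,
#'   ns, and the p-value (`NA` when a group is degenerate).
#' @export
compare_demographics <- function(meta) {
  meta <- meta[meta$group %in% c("depression", "control"), , drop = FALSE]
  vars <- c(age = "welch", bmi = "welch", cesd = "wilcoxon")
  rows <- list()
  for (sx in unique(as.character(meta$sex))) {
    m <- meta[meta$sex == sx, , drop = FALSE]
    dep <- m[m$group == "depression", , drop = FALSE]
    ctl <- m[m$group == "control", , drop = FALSE]
    if (nrow(dep) < 2L || nrow(ctl) < 2L)
      stopf("need >= 2 samples per group for sex '%s'", sx)
    for (v in names(vars)) {
      if (!v %in% names(m)) next
      x <- dep[[v]]; y <- ctl[[v]]
      p <- tryCatch({
        if (vars[[v]] == "welch") t.test(x, y, var.equal = FALSE)$p.value
        else wilcox.test(x, y, exact = (length(x) <= 25 && length(y) <= 25 &&
                                          !anyDuplicated(c(x, y))))$p.value
      }, error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        sex = sx, variable = v, test = vars[[v]],
        depression_mean = mean(x), depression_sd = sd(x), depression_n = length(x),
        control_mean = mean(y), control_sd = sd(y), control_n = length(y),
        p_value = p)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.screening_audit <- function(x, ...) {
  cat("Screening audit:", x$n_input, "in,", x$n_remaining, "remaining\n")
  for (nm in names(x$removed))
    cat(sprintf("  %-20s %d\n", nm, x$removed[[nm]]))
  invisible(x)
}
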
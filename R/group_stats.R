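#' Two-tailed Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact p-value when both samples have at most 8 observations and there
#' are no ties; otherwise the normal approximation with the standard
#' tie-corrected variance and no continuity correction. If every value in
#' the two samples is identical the samples are indistinguishable and p is
#' 1.
#'
#' @param a,b numeric vectors (nonempty).
#' @return two-tailed p-value.
#' @examples
#' mann_whitney_two_tailed(c(1, 2, 3), c(4, 5, 6))  # 0.1
#' @export
mann_whitney_two_tailed <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be nonempty")
  pool <- c(a, b)
  if (length(unique(pool)) == 1L) return(1)
  exact <- max(length(a), length(b)) <= 8L && !anyDuplicated(pool)
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE)$p.value)
  if (is.nan(p)) 1 else min(p, 1)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha_family family-wise error rate in (0,1).
#' @param n_tests number of tests in the family (>= 1).
#' @return per-test threshold \code{alpha_family / n_tests}; e.g. testing
#'   six UTR positions at the 99\% level gives 0.01/6 < 0.0017.
#' @export
bonferroni_threshold <- function(alpha_family, n_tests) {
  stopifnot(alpha_family > 0, alpha_family < 1, n_tests >= 1)
  alpha_family / n_tests
}

#' Average SCO profiles into a composite pseudo-organism
#'
#' Position-wise arithmetic mean of the per-position SCOs and of the
#' combined SCO, used e.g. to collapse several congeneric species into a
#' single composite so one well-sampled genus does not dominate a group
#' comparison. Missing per-position scores are dropped from the mean at
#' that position.
#'
#' @param profiles list of [sco_profile()] objects with matching position
#'   counts.
#' @param label label for the composite.
#' @return a \code{sco_profile} (count fields summed across members).
#' @export
composite_average <- function(profiles, label = "composite") {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "sco_profile")))
  np <- vapply(profiles, function(p) length(p$sco), integer(1))
  if (length(unique(np)) != 1L) stop("profiles have mismatched position counts")
  sco_mat <- do.call(rbind, lapply(profiles, `[[`, "sco"))
  structure(list(
    organism = label,
    sco = colMeans(sco_mat, na.rm = TRUE),
    combined_sco = mean(vapply(profiles, `[[`, numeric(1), "combined_sco")),
    frac_obs = mean(vapply(profiles, `[[`, numeric(1), "frac_obs")),
    frac_exp = mean(vapply(profiles, `[[`, numeric(1), "frac_exp")),
    obs = colSums(do.call(rbind, lapply(profiles, `[[`, "obs"))),
    exp = colSums(do.call(rbind, lapply(profiles, `[[`, "exp"))),
    q = colMeans(do.call(rbind, lapply(profiles, `[[`, "q"))),
    p_stop = mean(vapply(profiles, `[[`, numeric(1), "p_stop")),
    n_genes = sum(vapply(profiles, `[[`, integer(1), "n_genes")),
    n_with_tsc = sum(vapply(profiles, `[[`, integer(1), "n_with_tsc"))),
    class = "sco_profile")
}

#' Compare SCO distributions across organism groups
#'
#' For every pair of groups and every UTR position, runs a two-tailed
#' Mann-Whitney test on the per-organism SCOs at that position and flags
#' p-values below the Bonferroni threshold
#' \code{alpha_family / n_positions}. Missing per-organism scores at a
#' position are dropped from that comparison.
#'
#' @param groups named list: group label -> list of [sco_profile()]
#'   objects (one per organism). Groups with fewer than 2 organisms are
#'   dropped with a warning; at least 2 usable groups are required.
#' @param alpha_family family-wise error rate (default 0.01, i.e. the 99\%
#'   level).
#' @param n_positions number of UTR positions compared (default 6).
#' @return An object of class \code{group_table}: list with
#'   \code{comparisons} (data frame: group_a, group_b, position, n_a, n_b,
#'   p_value, significant) and \code{alpha_corrected}.
#' @export
compare_groups <- function(groups, alpha_family = 0.01, n_positions = 6L) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L)) {
    warning("dropping group(s) with < 2 organisms: ",
            paste(names(groups)[sizes < 2L], collapse = ", "))
    groups <- groups[sizes >= 2L]
  }
  if (length(groups) < 2L) stop("need at least 2 groups with >= 2 organisms")
  thr <- bonferroni_threshold(alpha_family, n_positions)

  sco_at <- function(grp, i)
    vapply(grp, function(p) p$sco[i], numeric(1))
  labels <- names(groups)
  rows <- list()
  for (ai in seq_len(length(labels) - 1L)) {
    for (bi in (ai + 1L):length(labels)) {
      for (i in seq_len(n_positions)) {
        va <- sco_at(groups[[ai]], i); vb <- sco_at(groups[[bi]], i)
        va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
        if (!length(va) || !length(vb)) {
          p <- NA_real_
        } else {
          p <- mann_whitney_two_tailed(va, vb)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          group_a = labels[ai], group_b = labels[bi], position = i,
          n_a = length(va), n_b = length(vb), p_value = p,
          significant = !is.na(p) & p < thr, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(comparisons = do.call(rbind, rows), alpha_corrected = thr,
                 alpha_family = alpha_family),
            class = "group_table")
}

#' @export
print.group_table <- function(x, ...) {
  cat("Group comparisons (Mann-Whitney, two-tailed); Bonferroni threshold ",
      signif(x$alpha_corrected, 4), "\n", sep = "")
  print(x$comparisons)
  invisible(x)
}

#' Write a group comparison table as TSV
#'
#' @param table a [compare_groups()] result.
#' @param path output path.
#' @export
write_group_table <- function(table, path) {
  stopifnot(inherits(table, "group_table"))
  utils::write.table(table$comparisons, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
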
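#' Aggregate leaf measurements through the nested replicate design
#'
#' Implements two-stage averaging over the nested sampling design
#' (line scans within images within biological replicates within groups):
#' all technical measurements within a biological replicate are averaged
#' into one replicate mean, and group statistics are computed on the
#' unweighted replicate means. Image-level summaries are also reported.
#' Every summary level carries `n`, `mean`, sample `sd` (n-1 denominator)
#' and `cv_pct = 100 * sd / mean`.
#'
#' @param leaves A tibble of leaf measurements with columns `group`,
#'   `replicate`, `image`, `scan`, `measure` (and optionally `pair`) and
#'   `value_nm`. Rows with missing values are flagged and excluded.
#' @return A `nested_measures` list: `leaves` and summary tibbles
#'   `by_image`, `by_replicate`, `by_group`.
#' @examples
#' leaves <- tibble::tibble(group = "a", replicate = rep(1:2, each = 2),
#'                          image = 1, scan = rep(1:2, 2),
#'                          measure = "length", value_nm = c(2, 2, 4, 4))
#' aggregate_measures(leaves)$by_group
#' @export
aggregate_measures <- function(leaves) {
  need <- c("group", "replicate", "image", "scan", "measure", "value_nm")
  if (!all(need %in% names(leaves))) {
    abort(paste0("`leaves` needs columns ", paste(need, collapse = ", "), "."))
  }
  if (!"pair" %in% names(leaves)) leaves$pair <- NA_character_
  n_bad <- sum(!is.finite(leaves$value_nm))
  if (n_bad > 0) {
    warn(sprintf("%d non-finite leaf value(s) excluded from aggregation.", n_bad))
    leaves <- dplyr::filter(leaves, is.finite(.data$value_nm))
  }
  summarise_level <- function(df, ...) {
    dplyr::summarise(dplyr::group_by(df, ...),
                     n = dplyr::n(),
                     mean_nm = mean(.data$value_nm),
                     sd_nm = sd(.data$value_nm),
                     cv_pct = 100 * sd(.data$value_nm) / mean(.data$value_nm),
                     .groups = "drop")
  }
  by_image <- summarise_level(leaves, .data$group, .data$replicate,
                              .data$image, .data$measure, .data$pair)
  by_replicate <- summarise_level(leaves, .data$group, .data$replicate,
                                  .data$measure, .data$pair)
  by_group <- dplyr::summarise(
    dplyr::group_by(by_replicate, .data$group, .data$measure, .data$pair),
    n_replicates = dplyr::n(),
    n_leaves = sum(.data$n),
    # statistics over the unweighted replicate means (sd before mean:
    # summarise evaluates sequentially and mean_nm is reassigned)
    sd_nm = sd(.data$mean_nm),
    cv_pct = 100 * sd(.data$mean_nm) / mean(.data$mean_nm),
    mean_nm = mean(.data$mean_nm),
    .groups = "drop")
  by_group <- dplyr::relocate(by_group, "mean_nm", .before = "sd_nm")
  structure(list(leaves = leaves, by_image = by_image,
                 by_replicate = by_replicate, by_group = by_group),
            class = "nested_measures")
}

#' @export
print.nested_measures <- function(x, ...) {
  cat(sprintf("<nested_measures> %d leaves, %d replicate rows, %d group rows\n",
              nrow(x$leaves), nrow(x$by_replicate), nrow(x$by_group)))
  print(x$by_group)
  invisible(x)
}

#' @rdname aggregate_measures
#' @param x A `nested_measures`.
#' @param level `"group"`, `"replicate"` or `"image"`.
#' @param ... Unused.
#' @method tidy nested_measures
#' @export
tidy.nested_measures <- function(x, level = c("group", "replicate", "image"),
                                 ...) {
  level <- match.arg(level)
  switch(level, group = x$by_group, replicate = x$by_replicate,
         image = x$by_image)
}

#' @rdname aggregate_measures
#' @method glance nested_measures
#' @export
glance.nested_measures <- function(x, ...) {
  tibble::tibble(n_groups = dplyr::n_distinct(x$leaves$group),
                 n_replicates = nrow(dplyr::distinct(
                   x$leaves, .data$group, .data$replicate)),
                 n_leaves = nrow(x$leaves),
                 n_measures = dplyr::n_distinct(x$leaves$measure))
}

#' Compare groups with the nested design's statistics
#'
#' Two-sample designs are compared with a Welch t-test on the biological
#' replicate means plus an F-test of variance homogeneity (on the raw leaf
#' measurements by default, with the replicate-mean version also reported).
#' Multi-group designs use a one-way ANOVA on replicate means — the
#' nesting is realized by aggregating technical replicates first, which is
#' exactly equivalent to a nested one-way ANOVA for balanced designs and
#' conservative otherwise — followed by Holm-adjusted pairwise Welch
#' t-tests.
#'
#' @param nm A [aggregate_measures()] result, or a leaf tibble.
#' @param measure Which measure to compare (default `"length"`).
#' @param pair Epitope pair to compare when `measure` is
#'   `"epitope_distance"`.
#' @param design `"auto"` (by number of groups), `"two_sample"` or
#'   `"multi"`.
#' @return A `group_comparison` list with a `tests` tibble
#'   (`test`, `statistic`, `df1`, `df2`, `p_value`, `comparison`,
#'   `p_adjust`), the replicate means used, and the design.
#' @export
compare_groups <- function(nm, measure = "length", pair = NULL,
                           design = c("auto", "two_sample", "multi")) {
  design <- match.arg(design)
  if (!inherits(nm, "nested_measures")) nm <- aggregate_measures(nm)
  leaves <- dplyr::filter(nm$leaves, .data$measure == !!measure)
  reps <- dplyr::filter(nm$by_replicate, .data$measure == !!measure)
  if (!is.null(pair)) {
    leaves <- dplyr::filter(leaves, .data$pair == !!pair)
    reps <- dplyr::filter(reps, .data$pair == !!pair)
  }
  groups <- unique(reps$group)
  if (length(groups) < 2) abort("need at least 2 groups to compare.")
  per_group_n <- table(reps$group)
  if (any(per_group_n < 2)) {
    abort("insufficient replication: every group needs >= 2 replicate means.")
  }
  if (design == "auto") {
    design <- if (length(groups) == 2) "two_sample" else "multi"
  }

  # identical or zero-variance samples make the classical tests
  # degenerate; report a null result (no evidence of difference) instead
  # of failing
  safe_test <- function(fn, x, y, null_stat) {
    tryCatch(fn(x, y), error = function(e) {
      list(statistic = null_stat, parameter = c(NA_real_, NA_real_),
           p.value = if (isTRUE(all.equal(mean(x), mean(y)))) 1 else NA_real_)
    })
  }
  if (design == "two_sample") {
    if (length(groups) != 2) abort("two_sample design requires exactly 2 groups.")
    m1 <- reps$mean_nm[reps$group == groups[1]]
    m2 <- reps$mean_nm[reps$group == groups[2]]
    tt <- safe_test(t.test, m1, m2, null_stat = 0)
    l1 <- leaves$value_nm[leaves$group == groups[1]]
    l2 <- leaves$value_nm[leaves$group == groups[2]]
    ft <- safe_test(var.test, l1, l2, null_stat = 1)
    ftr <- safe_test(var.test, m1, m2, null_stat = 1)
    tests <- tibble::tibble(
      test = c("welch_t_replicate_means", "f_variance_leaves",
               "f_variance_replicate_means"),
      comparison = paste(groups[1], "vs", groups[2]),
      statistic = c(unname(tt$statistic), unname(ft$statistic),
                    unname(ftr$statistic)),
      df1 = c(unname(tt$parameter[1]), unname(ft$parameter[1]),
              unname(ftr$parameter[1])),
      df2 = c(NA, unname(ft$parameter[2]), unname(ftr$parameter[2])),
      p_value = c(tt$p.value, ft$p.value, ftr$p.value),
      p_adjust = NA_real_)
  } else {
    fit <- aov(mean_nm ~ group, data = reps)
    an <- summary(fit)[[1]]
    ph <- pairwise.t.test(reps$mean_nm, reps$group, pool.sd = FALSE,
                          p.adjust.method = "holm")
    pw <- as.data.frame(as.table(ph$p.value))
    pw <- pw[!is.na(pw$Freq), ]
    tests <- dplyr::bind_rows(
      tibble::tibble(test = "anova_replicate_means", comparison = "all groups",
                     statistic = an[["F value"]][1],
                     df1 = an[["Df"]][1], df2 = an[["Df"]][2],
                     p_value = an[["Pr(>F)"]][1], p_adjust = NA_real_),
      tibble::tibble(test = "pairwise_welch_holm",
                     comparison = paste(pw$Var1, "vs", pw$Var2),
                     statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                     p_value = NA_real_, p_adjust = pw$Freq))
  }
  structure(list(tests = tests, replicate_means = reps, design = design,
                 measure = measure, pair = pair),
            class = "group_comparison")
}

#' @rdname compare_groups
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$tests

#' @rdname compare_groups
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  main <- x$tests[1, ]
  tibble::tibble(design = x$design, measure = x$measure,
                 n_groups = dplyr::n_distinct(x$replicate_means$group),
                 statistic = main$statistic, p_value = main$p_value)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s design on '%s' (replicate means)\n",
              x$design, x$measure))
  print(x$tests)
  invisible(x)
}
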
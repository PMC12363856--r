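# Physical label volumes and per-organ Welch t-tests. Volumes are voxel
# counts times the voxel volume, reported in mm^3; the group comparison is
# the unequal-variance (Welch) two-sample t-test, which is also what base
# R's t.test computes by default.

#' Physical volumes of label regions
#'
#' @param labels a [label_image()].
#' @param subject_id identifier recorded in the table.
#' @param organ_names optional named character vector (names = label ids).
#' @param all_labels optional integer vector of labels that must appear in
#'   the table even when absent from the image (volume 0).
#' @return data.frame with columns `subject`, `label`, `organ`,
#'   `volume_mm3`.
#' @export
label_volume_table <- function(labels, subject_id = "subject",
                               organ_names = NULL, all_labels = NULL) {
  stopifnot(is_label_image(labels))
  vv <- grid_voxel_volume(labels$grid)
  present <- label_set(labels)
  labs <- sort(union(present, as.integer(all_labels)))
  counts <- tabulate(as.vector(labels$values), nbins = max(labs, 1L))
  vol <- vapply(labs, function(l) counts[l] * vv, numeric(1))
  organ <- as.character(labs)
  if (!is.null(organ_names)) {
    m <- match(as.character(labs), names(organ_names))
    organ[!is.na(m)] <- organ_names[m[!is.na(m)]]
  }
  data.frame(subject = subject_id, label = labs, organ = organ,
             volume_mm3 = vol, stringsAsFactors = FALSE)
}

#' Welch t-test from summary statistics
#'
#' Unequal-variance two-sample t-test computed from group means, standard
#' deviations and sizes: `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from
#' Student's t distribution. Reproduces printed per-organ p-values from
#' published mean (sd) summaries.
#'
#' @param m1,s1,n1 mean, sd, size of group 1.
#' @param m2,s2,n2 mean, sd, size of group 2.
#' @return List of class `welch_result` with `t`, `df`, `p`,
#'   `mean_difference`.
#' @export
welch_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("welch_t_from_summary: need n >= 2 per group")
  if (s1 < 0 || s2 < 0) stop("welch_t_from_summary: sd must be >= 0")
  if (s1 == 0 && s2 == 0)
    stop("welch_t_from_summary: both variances zero; test undefined")
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  structure(list(t = t, df = df, p = p, mean_difference = m1 - m2),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("welch: t = %.4g, df = %.3g, p = %.4g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Per-organ Welch tests between two volume tables
#'
#' @param table_a,table_b volume tables (see [label_volume_table()],
#'   possibly row-bound over subjects) for the two groups.
#' @return data.frame with one row per shared organ: per-group mean, sd, n,
#'   `t`, `df`, `p`. Organs with fewer than 2 subjects in either group are
#'   skipped with a warning.
#' @export
group_volume_tests <- function(table_a, table_b) {
  shared <- intersect(unique(table_a$label), unique(table_b$label))
  rows <- list()
  for (l in shared) {
    va <- table_a$volume_mm3[table_a$label == l]
    vb <- table_b$volume_mm3[table_b$label == l]
    if (length(va) < 2 || length(vb) < 2) {
      warning("group_volume_tests: organ ", l,
              " has < 2 subjects in a group; skipped")
      next
    }
    organ <- table_a$organ[table_a$label == l][1]
    if (sd(va) == 0 && sd(vb) == 0 && mean(va) == mean(vb)) {
      w <- list(t = 0, df = length(va) + length(vb) - 2, p = 1)
    } else {
      w <- welch_t_from_summary(mean(va), sd(va), length(va),
                                mean(vb), sd(vb), length(vb))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      label = l, organ = organ,
      mean_a = mean(va), sd_a = sd(va), n_a = length(va),
      mean_b = mean(vb), sd_b = sd(vb), n_b = length(vb),
      t = w$t, df = w$df, p = w$p, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
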
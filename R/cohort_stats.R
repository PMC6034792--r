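#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the sample against a normal distribution with the
#' sample's own mean and standard deviation. Used as the routing gate of the
#' group-comparison decision tree.
#'
#' @param sample numeric vector, `n >= 5`, non-degenerate.
#' @return A `test_result` with `test_name = "KS_normality"`.
#' @export
ks_normality <- function(sample) {
  sample <- as.numeric(sample)
  if (length(sample) < 5) stop("need at least 5 observations for KS")
  s <- stats::sd(sample)
  if (!is.finite(s) || s == 0)
    stop("degenerate (zero-variance) sample: normality is undefined")
  ks <- suppressWarnings(
    stats::ks.test(sample, "pnorm", mean = mean(sample), sd = s))
  test_result("KS_normality", unname(ks$statistic), ks$p.value,
              sprintf("one-sample KS vs Normal(%.4g, %.4g), n = %d",
                      mean(sample), s, length(sample)))
}

#' Two-group comparison with the paper-style routing
#'
#' If both groups pass the KS normality check at `alpha` and an F-ratio test
#' finds the variances homogeneous, the means are compared with Student's t
#' test (equal variances). Otherwise the comparison falls back to the
#' non-parametric Kruskal-Wallis test on the two groups. The route taken is
#' recorded in `decision_path`.
#'
#' @param g1,g2 numeric vectors, each `n >= 5`.
#' @param alpha significance level for the precondition checks.
#' @return A `test_result`; `test_name` is `"Student_t"` or
#'   `"Kruskal_Wallis"`.
#' @export
compare_two_groups <- function(g1, g2, alpha = 0.05) {
  if (length(g1) < 5 || length(g2) < 5)
    stop("each group needs at least 5 observations")
  path <- character(0)
  normal <- vapply(list(g1, g2), function(g) {
    p <- ks_normality(g)$p_value
    p > alpha
  }, logical(1))
  path <- c(path, sprintf("KS normality: group1 %s, group2 %s",
                          ifelse(normal, "pass", "fail")[1],
                          ifelse(normal, "pass", "fail")[2]))
  if (all(normal)) {
    vr <- stats::var.test(g1, g2)
    homo <- vr$p.value > alpha
    path <- c(path, sprintf("variance homogeneity (F-ratio): %s (p = %.3g)",
                            if (homo) "pass" else "fail", vr$p.value))
    if (homo) {
      tt <- stats::t.test(g1, g2, var.equal = TRUE)
      path <- c(path, "route: Student t (equal variances)")
      return(test_result("Student_t", unname(tt$statistic), tt$p.value,
                         paste(path, collapse = "; ")))
    }
  }
  kw <- stats::kruskal.test(list(g1, g2))
  path <- c(path, "route: Kruskal-Wallis (non-parametric fallback)")
  test_result("Kruskal_Wallis", unname(kw$statistic), kw$p.value,
              paste(path, collapse = "; "))
}

#' Multi-group comparison (three or more groups)
#'
#' All groups normal by the KS check: one-way F test of equal means (ANOVA,
#' equal variances) — the test of whether at least one group's mean deviates
#' from the others. Any group non-normal: Kruskal-Wallis.
#'
#' @param groups list of `>= 3` numeric vectors, each `n >= 5`.
#' @param alpha significance level for the normality gate.
#' @return A `test_result`; `test_name` is `"F_equal_means"` or
#'   `"Kruskal_Wallis"`.
#' @export
compare_multi_groups <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 3)
    stop("need a list of at least 3 groups")
  if (any(vapply(groups, length, integer(1)) < 5))
    stop("each group needs at least 5 observations")
  normal <- vapply(groups, function(g) ks_normality(g)$p_value > alpha,
                   logical(1))
  path <- sprintf("KS normality: %d / %d groups pass", sum(normal),
                  length(groups))
  values <- unlist(groups)
  fac <- factor(rep(seq_along(groups), lengths(groups)))
  if (all(normal)) {
    ow <- stats::oneway.test(values ~ fac, var.equal = TRUE)
    path <- c(path, "route: one-way F test of equal means")
    test_result("F_equal_means", unname(ow$statistic), ow$p.value,
                paste(path, collapse = "; "))
  } else {
    kw <- stats::kruskal.test(values, fac)
    path <- c(path, "route: Kruskal-Wallis")
    test_result("Kruskal_Wallis", unname(kw$statistic), kw$p.value,
                paste(path, collapse = "; "))
  }
}

test_result <- function(test_name, statistic, p_value, decision_path) {
  stopifnot(nzchar(decision_path))
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, decision_path = decision_path),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4f, p = %.4g\n  [%s]\n", x$test_name,
              x$statistic, x$p_value, x$decision_path))
  invisible(x)
}

#' Glaucoma staging by visual-field mean deviation
#'
#' Hoddap-Parrish-Anderson grading: stage 0 = normal visual field; stage 1
#' (early defect) `MD >= -6.00` dB with an abnormal field; stage 2 (moderate)
#' `-12.00 <= MD < -6.00`; stage 3 (advanced) `-20.00 < MD < -12.00`; stage 4
#' (severe) `MD <= -20.00`; stage 5 = patient unable to perform the visual
#' field test. Boundary values go to stage 2 at `-12.00` and stage 4 at
#' `-20.00` (the printed scale's `-12.01` gap is closed on the stage-2 side);
#' the staging is monotone: a lower MD never gives a lower stage.
#'
#' @param md_db visual-field mean deviation in dB (finite when
#'   `vf_performed`).
#' @param vf_performed was the visual-field test performed?
#' @param field_normal is the visual field normal (stage 0)?
#' @return A `glaucoma_stage` object with fields `stage`, `md_db`,
#'   `vf_performed`.
#' @export
classify_glaucoma_stage <- function(md_db, vf_performed = TRUE,
                                    field_normal = FALSE) {
  if (!vf_performed) {
    stage <- 5L
    md_db <- NA_real_
  } else {
    if (!is.finite(md_db)) stop("`md_db` must be finite when the visual field was performed")
    stage <- if (field_normal) 0L
      else if (md_db >= -6) 1L
      else if (md_db >= -12) 2L
      else if (md_db > -20) 3L
      else 4L
  }
  structure(list(stage = stage, md_db = md_db, vf_performed = vf_performed),
            class = "glaucoma_stage")
}

#' @export
print.glaucoma_stage <- function(x, ...) {
  labels <- c("normal visual field", "early defect", "moderate defect",
              "advanced defect", "severe defect", "end stage disease")
  cat(sprintf("glaucoma stage %d (%s)%s\n", x$stage, labels[x$stage + 1],
              if (x$vf_performed) sprintf(", MD = %.2f dB", x$md_db) else ""))
  invisible(x)
}
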
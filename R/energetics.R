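# Replicate-level statistics over MM/GBSA component tables. The energies
# themselves are inputs (computed upstream by an MM/GBSA engine); this module
# provides the summary and inference layer.

.ENERGY_COMPONENTS <- c("dG_bind", "dE_vdW", "dE_Coulomb", "dG_Lipo",
                        "dG_SolvGB", "E_StrainLig")

#' Validate a per-replicate energy table
#'
#' @param x data.frame (or CSV path) with columns `system`, `replicate`,
#'   `component`, `value` (kcal/mol); components must come from the closed
#'   set dG_bind, dE_vdW, dE_Coulomb, dG_Lipo, dG_SolvGB, E_StrainLig.
#' @return The validated data.frame, classed `energy_table`.
#' @export
energy_table <- function(x) {
  if (is.character(x)) x <- utils::read.csv(x, stringsAsFactors = FALSE)
  need <- c("system", "replicate", "component", "value")
  if (!all(need %in% names(x)))
    stop("energy table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(x$component), .ENERGY_COMPONENTS)
  if (length(bad))
    stop("unknown energy component(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(x$value)))
    stop("energy values must be finite", call. = FALSE)
  class(x) <- c("energy_table", "data.frame")
  x
}

#' Per-system mean and standard deviation of each energy component
#'
#' Sample standard deviation (n - 1 denominator), ordered by the canonical
#' component order (total binding energy first, then its decomposition).
#'
#' @param table an [energy_table()] (or coercible data.frame/CSV path).
#' @return data.frame `system`, `component`, `mean`, `sd`, `n`, classed
#'   `energy_summary`.
#' @export
summarize_energetics <- function(table) {
  table <- energy_table(table)
  grp <- split(table, list(table$system, table$component), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(g) {
    if (nrow(g) < 2)
      stop(sprintf("SD undefined: system '%s' has a single replicate for %s",
                   g$system[1], g$component[1]), call. = FALSE)
    data.frame(system = g$system[1], component = g$component[1],
               mean = mean(g$value), sd = stats::sd(g$value), n = nrow(g),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(match(out$component, .ENERGY_COMPONENTS), out$system), ]
  rownames(out) <- NULL
  class(out) <- c("energy_summary", "data.frame")
  out
}

#' Two-sample t-test from summary statistics
#'
#' Pooled (default): sp^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2),
#' t = (mean1 - mean2) / (sp sqrt(1/n1 + 1/n2)), df = n1 + n2 - 2.
#' Welch: Welch-Satterthwaite df. Two-sided p from the Student t
#' distribution. With zero pooled variance: equal means give the degenerate
#' convention t = 0, p = 1; unequal means are an error.
#'
#' @param mean1,sd1,n1 summary of sample 1 (n >= 2, sd >= 0).
#' @param mean2,sd2,n2 summary of sample 2.
#' @param method `"pooled"` or `"welch"`.
#' @return Object of class `comparison_result`: `mean_diff`, `t`, `df`, `p`,
#'   `method`.
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               method = c("pooled", "welch")) {
  method <- match.arg(method)
  if (n1 < 2 || n2 < 2) stop("both samples need n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0", call. = FALSE)
  diff <- mean1 - mean2
  if (method == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  if (se == 0) {
    if (abs(diff) < .Machine$double.eps^0.5) {
      t <- 0; p <- 1
    } else {
      stop("degenerate variance: zero spread with unequal means", call. = FALSE)
    }
  } else {
    t <- diff / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(mean_diff = diff, t = t, df = df, p = p, method = method),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Two-sample t-test (%s): mean diff %.2f kcal/mol, t = %.3f, df = %.2f, p = %.3f\n",
              x$method, x$mean_diff, x$t, x$df, x$p))
  invisible(x)
}

#' Absolute mean difference of one component between two systems
#'
#' @param summary an `energy_summary` (from [summarize_energetics()]) or an
#'   [energy_table()] to summarize first.
#' @param system_a,system_b system labels.
#' @param component energy component (default total `dG_bind`).
#' @return |mean_a - mean_b| in kcal/mol.
#' @export
mean_difference <- function(summary, system_a, system_b,
                            component = "dG_bind") {
  if (!inherits(summary, "energy_summary"))
    summary <- summarize_energetics(summary)
  pick <- function(sys) {
    row <- summary[summary$system == sys & summary$component == component, ]
    if (nrow(row) != 1L)
      stop("lookup error: no unique entry for system '", sys,
           "', component '", component, "'", call. = FALSE)
    row
  }
  abs(pick(system_a)$mean - pick(system_b)$mean)
}

#' Compare one component between two systems from summary rows
#'
#' Convenience wrapper running [ttest_from_summary()] on the rows of an
#' `energy_summary`.
#'
#' @inheritParams mean_difference
#' @param method `"pooled"` or `"welch"`.
#' @return A `comparison_result`.
#' @export
compare_systems <- function(summary, system_a, system_b,
                            component = "dG_bind", method = "pooled") {
  if (!inherits(summary, "energy_summary"))
    summary <- summarize_energetics(summary)
  row <- function(sys) {
    r <- summary[summary$system == sys & summary$component == component, ]
    if (nrow(r) != 1L)
      stop("lookup error: no unique entry for system '", sys, "'", call. = FALSE)
    r
  }
  a <- row(system_a); b <- row(system_b)
  ttest_from_summary(a$mean, a$sd, a$n, b$mean, b$sd, b$n, method = method)
}

#' Published MM/GBSA summary for the SESN2-BCAA systems
#'
#' Mean +/- SD (kcal/mol) of the total binding free energy and its
#' decomposition for the leucine-, isoleucine- and valine-bound Sestrin2
#' complexes, each over three independent 500 ns replicate simulations.
#' Shipped as a plain-text table; the package computes all statistics from
#' it at run time.
#'
#' @return An `energy_summary` data.frame (`system`, `component`, `mean`,
#'   `sd`, `n`).
#' @export
sesn2_mmgbsa <- function() {
  path <- system.file("extdata", "sesn2_mmgbsa_summary.csv",
                      package = "conflock", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("energy_summary", "data.frame")
  out
}

#' Simulate replicate energy values matching a summary
#'
#' Draws `n` normal replicate values per (system, component) row; useful for
#' checking that the summary/statistics layer inverts generation.
#'
#' @param summary an `energy_summary`.
#' @param seed integer seed.
#' @return An [energy_table()].
#' @export
simulate_energy_table <- function(summary, seed = 1) {
  stopifnot(inherits(summary, "energy_summary"))
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(nrow(summary)), function(i) {
    r <- summary[i, ]
    data.frame(system = r$system, replicate = seq_len(r$n),
               component = r$component,
               value = stats::rnorm(r$n, r$mean, r$sd),
               stringsAsFactors = FALSE)
  }))
  energy_table(out)
}
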
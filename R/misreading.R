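#' Expected label-incorporation fold change under misreading
#'
#' First-order incorporation model. Every cognate codon of label X
#' incorporates X; every near-cognate codon of X incorporates X with the
#' per-event misreading probability `epsilon`. The expected labelled
#' residue counts per molecule are
#' \deqn{E[A] = C_A + \epsilon NC_A, \quad E[B] = C_B + \epsilon NC_B,}
#' and the A/B incorporation ratio, normalised so that a perfectly
#' accurate ribosome gives 1, is
#' \deqn{f(\epsilon) = \frac{(C_A + \epsilon NC_A)/(C_B + \epsilon NC_B)}
#'   {C_A / C_B}.}
#' Its slope at zero, `NC_A/C_A - NC_B/C_B`, is why a high
#' discrimination-ratio gene (MT-CO1: slope 94.5) responds to misreading
#' while a low-ratio gene (MT-CO2: slope about 3) barely moves.
#'
#' @param stats a `reporter_stats` (or anything with fields `c_a`,
#'   `nc_a`, `c_b`, `nc_b`).
#' @param epsilon per-near-cognate-event misreading probability in [0, 1].
#' @return an `incorporation_result`: list with `mean_count_a`,
#'   `mean_count_b`, `ratio_fold_change`, `epsilon`, `mc_stderr` (0 for
#'   the closed form), `method = "closed_form"`.
#' @examples
#' st <- reporter_ratio(1, 96, 32, 48)
#' expected_ratio_fold_change(st, 0.01)$ratio_fold_change  # 1.931
#' @export
expected_ratio_fold_change <- function(stats, epsilon) {
  check_counts_model(stats, epsilon)
  ea <- stats$c_a + epsilon * stats$nc_a
  eb <- stats$c_b + epsilon * stats$nc_b
  incorporation_result(ea, eb, (ea / eb) / (stats$c_a / stats$c_b),
                       epsilon, mc_stderr = 0, method = "closed_form")
}

check_counts_model <- function(stats, epsilon) {
  if (is.null(stats$c_a) || is.null(stats$c_b)) stop("stats must carry counts")
  if (stats$c_a == 0 || stats$c_b == 0) {
    stop("undefined: model requires at least one cognate codon per label")
  }
  stopifnot(all(epsilon >= 0), all(epsilon <= 1))
}

incorporation_result <- function(a, b, fc, epsilon, mc_stderr, method,
                                 n_molecules = NA_integer_) {
  structure(
    list(mean_count_a = a, mean_count_b = b, ratio_fold_change = fc,
         epsilon = epsilon, mc_stderr = mc_stderr, method = method,
         n_molecules = n_molecules),
    class = "incorporation_result"
  )
}

#' @export
print.incorporation_result <- function(x, ...) {
  cat("Incorporation model (", x$method, "), epsilon = ", x$epsilon, "\n",
      sep = "")
  cat(sprintf("  mean labelled counts: A = %.4f, B = %.4f\n",
              x$mean_count_a, x$mean_count_b))
  cat(sprintf("  ratio fold change = %.4f", x$ratio_fold_change))
  if (x$method == "monte_carlo") {
    cat(sprintf(" (MC stderr %.2g, n = %d)", x$mc_stderr, x$n_molecules))
  }
  cat("\n")
  invisible(x)
}

#' Monte Carlo simulation of per-molecule label incorporation
#'
#' Per-molecule counterpart of [expected_ratio_fold_change()]: for each of
#' `n_molecules` translation products, each cognate codon of a label
#' incorporates that label deterministically and each near-cognate codon
#' incorporates it independently with probability `epsilon`. The fold
#' change is the ratio of empirical mean counts, normalised by
#' `C_A / C_B`; its standard error comes from the delta method on the two
#' independent empirical means.
#'
#' @param stats a `reporter_stats` with the four counts (obtain from
#'   [reporter_ratio()] or [count_codons()] on a CDS and two
#'   neighbourhoods).
#' @param epsilon per-event misreading probability.
#' @param n_molecules number of simulated molecules.
#' @param seed integer seed; the run is fully reproducible given the seed.
#' @return an `incorporation_result` with `method = "monte_carlo"`.
#' @export
simulate_incorporation <- function(stats, epsilon, n_molecules = 1e5,
                                   seed = 1L) {
  check_counts_model(stats, epsilon)
  stopifnot(n_molecules >= 1)
  n <- as.integer(n_molecules)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  a <- stats$c_a + stats::rbinom(n, stats$nc_a, epsilon)
  b <- stats$c_b + stats::rbinom(n, stats$nc_b, epsilon)
  ma <- mean(a); mb <- mean(b)
  fc <- (ma / mb) / (stats$c_a / stats$c_b)
  # delta method for the ratio of independent means
  se <- if (epsilon == 0) 0 else
    fc * sqrt(stats::var(a) / (n * ma^2) + stats::var(b) / (n * mb^2))
  incorporation_result(ma, mb, fc, epsilon, mc_stderr = se,
                       method = "monte_carlo", n_molecules = n)
}

#' Recover the misreading probability from an observed fold change
#'
#' Inverts the first-order incorporation model: finds the unique epsilon
#' in [0, 1] with `expected_ratio_fold_change(stats, epsilon) ==
#' observed_fold_change`, by a bracketed monotone root solve. The model
#' fold change is strictly increasing in epsilon exactly when
#' `NC_A/C_A > NC_B/C_B`.
#'
#' @param observed_fold_change observed normalised A/B ratio (>= 1 and
#'   <= the model value at epsilon = 1).
#' @param stats a `reporter_stats` with the four counts.
#' @param tol absolute tolerance on epsilon.
#' @return the epsilon estimate (double scalar).
#' @examples
#' st <- reporter_ratio(1, 96, 32, 48)
#' fit_epsilon(1.931, st)  # ~0.01
#' @export
fit_epsilon <- function(observed_fold_change, stats, tol = 1e-12) {
  check_counts_model(stats, 0)
  slope <- stats$nc_a / stats$c_a - stats$nc_b / stats$c_b
  if (slope <= 0) stop("fold change is not increasing in epsilon for these counts")
  fmax <- expected_ratio_fold_change(stats, 1)$ratio_fold_change
  if (observed_fold_change < 1 || observed_fold_change > fmax) {
    stop(sprintf("observed fold change %.4g outside the model range [1, %.4g]",
                 observed_fold_change, fmax))
  }
  if (observed_fold_change == 1) return(0)
  g <- function(e) expected_ratio_fold_change(stats, e)$ratio_fold_change -
    observed_fold_change
  stats::uniroot(g, c(0, 1), tol = tol)$root
}

#' Normalise dual-reporter assay replicates
#'
#' Computes per-replicate test/reference signal ratios (e.g. mutant
#' firefly over Renilla luciferase activity) in a test and a reference
#' group, and reports the fold change of mean ratios with the reference
#' group normalised to 1, each group with mean, SEM and n.
#'
#' @param test_group,reference_group data.frames with columns
#'   `test_signal` and `reference_signal` (one row per replicate, all
#'   signals positive).
#' @return a `dual_reporter_norm`: list with `fold_change`, `groups`
#'   (data.frame: group, n, mean_ratio, normalized_mean, sem), and
#'   `ratios` (list of the per-replicate normalised ratios).
#' @export
normalize_dual_reporter <- function(test_group, reference_group) {
  rt <- replicate_ratios(test_group, "test")
  rr <- replicate_ratios(reference_group, "reference")
  mr <- mean(rr)
  fold <- mean(rt) / mr
  norm <- list(test = rt / mr, reference = rr / mr)
  groups <- data.frame(
    group = c("test", "reference"),
    n = c(length(rt), length(rr)),
    mean_ratio = c(mean(rt), mean(rr)),
    normalized_mean = c(fold, 1),
    sem = c(stats::sd(norm$test) / sqrt(length(rt)),
            stats::sd(norm$reference) / sqrt(length(rr))),
    stringsAsFactors = FALSE
  )
  groups$sem[groups$n == 1L] <- 0
  structure(list(fold_change = fold, groups = groups, ratios = norm),
            class = "dual_reporter_norm")
}

replicate_ratios <- function(df, label) {
  if (!all(c("test_signal", "reference_signal") %in% names(df))) {
    stop(label, " group needs columns test_signal and reference_signal")
  }
  if (nrow(df) < 1L) stop(label, " group needs at least one replicate")
  if (any(df$test_signal <= 0) || any(df$reference_signal <= 0)) {
    stop("non-positive signal in ", label, " group")
  }
  df$test_signal / df$reference_signal
}

#' @export
print.dual_reporter_norm <- function(x, ...) {
  cat(sprintf("Dual-reporter normalisation: fold change = %.4f\n",
              x$fold_change))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Two-sample test on normalised dual-reporter ratios
#'
#' Convenience Welch t-test comparing per-replicate normalised ratios of
#' the test group against the reference group.
#'
#' @param norm a `dual_reporter_norm`.
#' @param var.equal passed to [stats::t.test()] (default FALSE: Welch).
#' @return an object of class `htest`.
#' @export
dual_reporter_t_test <- function(norm, var.equal = FALSE) {
  stopifnot(inherits(norm, "dual_reporter_norm"))
  stats::t.test(norm$ratios$test, norm$ratios$reference,
                var.equal = var.equal)
}
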
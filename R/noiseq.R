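#' NOISeq-sim: no-replicate differential expression by simulated replicates
#'
#' Non-parametric differential-expression assessment for a pair of
#' unreplicated count profiles. Zero counts are replaced by the pseudo-count
#' `k`, counts are scaled to reads-per-million of their sample depth and
#' optionally divided by feature length (kb). For each condition `nss`
#' technical pseudo-replicates are simulated by multinomial draws of depth
#' `pnr` times the condition total, jittered by a factor uniform in
#' `[1 - v, 1 + v]`. Each feature's signal is `M = log2(mean_a / mean_b)`
#' and `D = |mean_a - mean_b|` over the normalised replicate means; the
#' noise distribution pools the `(|M|, D)` pairs of all within-condition
#' replicate comparisons over all features. The differential-expression
#' probability is the fraction of noise pairs strictly dominated by the
#' feature's signal in both coordinates, and a feature is called when
#' `prob > prob_threshold`.
#'
#' @param counts_a,counts_b Non-negative integer count vectors over the same
#'   feature universe.
#' @param lengths Optional feature lengths (nt) for length normalisation.
#' @param feature_ids Optional feature names (defaults to names of
#'   `counts_a` or `f1..fn`).
#' @param k Pseudo-count replacing zeros (default 0.5).
#' @param nss Simulated replicates per condition (default 5, minimum 2).
#' @param pnr Fraction of the condition's depth per simulated replicate
#'   (default 0.2).
#' @param v Depth jitter half-width (default 0.02).
#' @param prob_threshold Call threshold on `prob` (default 0.9).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return A `noiseq_sim` object: list with `results` (tibble: `feature`,
#'   `count_a`, `count_b`, `M`, `D`, `prob`, `called`) and `params`.
#' @export
noiseq_sim <- function(counts_a, counts_b, lengths = NULL,
                       feature_ids = NULL, k = 0.5, nss = 5L, pnr = 0.2,
                       v = 0.02, prob_threshold = 0.9, seed = 1) {
  if (length(counts_a) != length(counts_b)) {
    abort("counts_a and counts_b must cover the same feature universe")
  }
  if (any(counts_a < 0) || any(counts_b < 0)) abort("counts must be >= 0")
  if (nss < 2L) abort("nss must be >= 2")
  if (pnr <= 0 || pnr > 1) abort("pnr must be in (0, 1]")
  if (v < 0) abort("v must be >= 0")
  if (prob_threshold <= 0 || prob_threshold >= 1) {
    abort("prob_threshold must be in (0, 1)")
  }
  nf <- length(counts_a)
  if (nf < 10L) {
    warn("fewer than 10 features: the noise distribution is unstable")
  }
  feature_ids <- feature_ids %||% names(counts_a) %||%
    sprintf("f%04d", seq_len(nf))
  len_kb <- if (is.null(lengths)) rep(1, nf) else lengths / 1e3

  normalise <- function(x, depth) {
    x[x == 0] <- k
    (x / depth) * 1e6 / len_kb
  }
  sim_condition <- function(counts) {
    total <- sum(counts)
    if (total <= 0) abort("a condition has zero total counts")
    sapply(seq_len(nss), function(r) {
      depth <- max(1, round(pnr * total * runif(1, 1 - v, 1 + v)))
      draw <- rmultinom(1, depth, counts / total)[, 1]
      normalise(draw, depth)
    })
  }
  with_seed(seed, {
    reps_a <- sim_condition(counts_a)
    reps_b <- sim_condition(counts_b)
    mean_a <- rowMeans(reps_a)
    mean_b <- rowMeans(reps_b)
    M <- log2(mean_a / mean_b)
    D <- abs(mean_a - mean_b)
    pairs <- utils::combn(nss, 2L)
    noise_of <- function(reps) {
      Mn <- Dn <- NULL
      for (p in seq_len(ncol(pairs))) {
        x <- reps[, pairs[1, p]]
        y <- reps[, pairs[2, p]]
        Mn <- c(Mn, log2(x / y))
        Dn <- c(Dn, abs(x - y))
      }
      list(M = Mn, D = Dn)
    }
    na_ <- noise_of(reps_a)
    nb_ <- noise_of(reps_b)
    noise_m <- abs(c(na_$M, nb_$M))
    noise_d <- c(na_$D, nb_$D)
    prob <- vapply(seq_len(nf), function(f) {
      mean(noise_m < abs(M[f]) & noise_d < D[f])
    }, numeric(1))
    results <- tibble(
      feature = feature_ids,
      count_a = counts_a, count_b = counts_b,
      M = M, D = D, prob = prob,
      called = prob > prob_threshold
    )
    structure(
      list(
        results = results,
        params = list(k = k, nss = nss, pnr = pnr, v = v,
                      prob_threshold = prob_threshold, seed = seed,
                      length_normalised = !is.null(lengths))
      ),
      class = "noiseq_sim"
    )
  })
}

#' @export
print.noiseq_sim <- function(x, ...) {
  cat(sprintf(
    "<noiseq_sim> %d features, %d called at prob > %.2f (nss = %d)\n",
    nrow(x$results), sum(x$results$called), x$params$prob_threshold,
    x$params$nss
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a NOISeq-sim fit
#'
#' @param x A `noiseq_sim` object.
#' @param ... Unused.
#' @return The per-feature results tibble.
#' @export
tidy.noiseq_sim <- function(x, ...) x$results

#' One-row summary of a NOISeq-sim fit
#'
#' @param x A `noiseq_sim` object.
#' @param ... Unused.
#' @return One-row tibble: feature and call counts plus the key parameters.
#' @export
glance.noiseq_sim <- function(x, ...) {
  tibble(
    n_features = nrow(x$results),
    n_called = sum(x$results$called),
    prob_threshold = x$params$prob_threshold,
    nss = x$params$nss,
    pnr = x$params$pnr,
    v = x$params$v
  )
}

#' M-D plot of a NOISeq-sim fit
#'
#' Scatter of each feature's absolute-difference statistic `D` (log10 axis)
#' against its log2 ratio `M`, coloured by differential call.
#'
#' @param object A `noiseq_sim` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.noiseq_sim <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = .data$D, y = .data$M,
                                   colour = .data$called)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey50", `TRUE` = "firebrick")
    ) +
    ggplot2::labs(
      x = "D (|difference| of normalised means)",
      y = "M (log2 ratio)",
      colour = sprintf("prob > %.2f", object$params$prob_threshold)
    ) +
    ggplot2::theme_minimal()
}
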
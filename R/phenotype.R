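#' Mixed-model specification for bull fertility estimation
#'
#' The bull effect is a random effect whose variance is a fixed ratio of the
#' phenotypic variance (default 0.01, the ratio used in national non-return
#' evaluations), which translates into a ridge term
#' `lambda_b = (1 - r_b) / r_b` on the bull equations of the mixed-model
#' equations. A random cow (permanent environment) effect can be enabled with
#' its own ratio; it is off by default.
#'
#' @param r_bull bull variance ratio `sigma2_bull / sigma2_phenotypic`,
#'   in (0, 1).
#' @param cow_effect include a random cow effect?
#' @param r_cow cow variance ratio, used when `cow_effect` is `TRUE`.
#' @return list of class `MixedModelSpec`.
#' @export
mixed_model_spec <- function(r_bull = 0.01, cow_effect = FALSE,
                             r_cow = 0.05) {
  if (r_bull <= 0 || r_bull >= 1) stop("'r_bull' must be in (0, 1)")
  if (cow_effect && (r_cow <= 0 || r_cow >= 1))
    stop("'r_cow' must be in (0, 1)")
  structure(list(r_bull = r_bull, cow_effect = cow_effect, r_cow = r_cow),
            class = "MixedModelSpec")
}

#' Estimate corrected non-return rates (bull BLUPs) from 0/1 AI scores
#'
#' Solves the mixed-model equations for the linear model
#' `score = fixed effects + random bull (+ random cow) + residual` applied
#' directly to the 0/1 non-return scores. Fixed effects are one-hot encoded
#' with the first level as reference and an always-included intercept; random
#' effects get the ridge term `lambda = (1 - r) / r` from their variance
#' ratio. The bull solutions are the "corrected NRR 56" phenotype: BLUPs
#' centered at 0 (their sum is exactly 0 whenever an intercept is estimable
#' and every bull has records).
#'
#' @param records data.frame with columns `bull_id`, `score` (0/1) and the
#'   fixed-effect columns named in `fixed_effects` (plus `cow_id` when the
#'   cow effect is enabled).
#' @param spec a [mixed_model_spec()].
#' @param fixed_effects character vector of fixed-effect column names;
#'   `NULL` selects every factor/character column other than identifiers.
#' @param all_bulls optional character vector of all bulls to report; bulls
#'   without records receive estimate 0 and are flagged.
#' @return data.frame `bull_id, estimate, n_records, flagged` (flagged bulls
#'   have zero records and an estimate fixed at 0); attribute `"intercept"`
#'   carries the estimated intercept and `"fixed_solutions"` the fixed-effect
#'   solutions.
#' @export
estimate_bull_effects <- function(records, spec = mixed_model_spec(),
                                  fixed_effects = NULL, all_bulls = NULL) {
  stopifnot(is.data.frame(records), "bull_id" %in% names(records),
            "score" %in% names(records))
  if (!all(records$score %in% c(0, 1))) stop("scores must be 0/1")
  bulls <- sort(unique(as.character(records$bull_id)))
  if (length(bulls) < 1L) stop("no bulls in records")
  if (is.null(fixed_effects))
    fixed_effects <- setdiff(names(records)[vapply(records, function(x)
      is.factor(x) || is.character(x), logical(1))],
      c("bull_id", "cow_id"))
  y <- as.numeric(records$score)
  nrec <- length(y)
  # fixed design: intercept + treatment-coded factors
  if (length(fixed_effects)) {
    fml <- stats::as.formula(paste("~", paste(fixed_effects, collapse = "+")))
    X <- Matrix::sparse.model.matrix(fml, data = records)
  } else {
    X <- Matrix::Matrix(1, nrec, 1, sparse = TRUE,
                        dimnames = list(NULL, "(Intercept)"))
  }
  qrX <- Matrix::qr(X)
  if (qrX@V@Dim[2] > 0 && any(abs(Matrix::diag(qrX@R)) < 1e-8)) {
    d <- abs(Matrix::diag(qrX@R))
    stop("singular fixed-effect design; confounded columns: ",
         paste(colnames(X)[qrX@q[which(d < 1e-8)] + 1L], collapse = ", "))
  }
  Zb <- Matrix::sparseMatrix(i = seq_len(nrec),
                             j = match(as.character(records$bull_id), bulls),
                             x = 1, dims = c(nrec, length(bulls)))
  lambda_b <- (1 - spec$r_bull) / spec$r_bull
  blocks <- list(X, Zb)
  ridges <- c(0, lambda_b)
  cows <- NULL
  if (isTRUE(spec$cow_effect)) {
    stopifnot("cow_id" %in% names(records))
    cows <- sort(unique(as.character(records$cow_id)))
    Zc <- Matrix::sparseMatrix(i = seq_len(nrec),
                               j = match(as.character(records$cow_id), cows),
                               x = 1, dims = c(nrec, length(cows)))
    blocks <- c(blocks, list(Zc))
    ridges <- c(ridges, (1 - spec$r_cow) / spec$r_cow)
  }
  W <- do.call(cbind, blocks)
  sizes <- vapply(blocks, ncol, integer(1))
  D <- Matrix::Diagonal(x = rep(ridges, sizes))
  lhs <- Matrix::crossprod(W) + D
  rhs <- Matrix::crossprod(W, y)
  sol <- as.numeric(Matrix::solve(lhs, rhs))
  p <- ncol(X)
  u <- sol[p + seq_along(bulls)]
  out <- data.frame(bull_id = bulls, estimate = u,
                    n_records = as.integer(tabulate(
                      match(as.character(records$bull_id), bulls),
                      length(bulls))),
                    flagged = FALSE, stringsAsFactors = FALSE)
  attr(out, "intercept") <- sol[1]
  attr(out, "fixed_solutions") <- stats::setNames(sol[seq_len(p)],
                                                  colnames(X))
  if (isTRUE(spec$cow_effect))
    attr(out, "cow_solutions") <- stats::setNames(
      sol[p + length(bulls) + seq_along(cows)], cows)
  extra <- setdiff(as.character(all_bulls %||% character()), out$bull_id)
  if (length(extra)) {
    at <- attributes(out)
    out <- rbind(out, data.frame(bull_id = extra, estimate = 0,
                                 n_records = 0L, flagged = TRUE))
    out <- out[order(out$bull_id), ]
    rownames(out) <- NULL
    attr(out, "intercept") <- at$intercept
    attr(out, "fixed_solutions") <- at$fixed_solutions
    if (!is.null(at$cow_solutions)) attr(out, "cow_solutions") <- at$cow_solutions
  }
  out
}

#' Assign fertility classes from per-bull effect estimates
#'
#' The study that motivates this package never publishes the numeric cut
#' separating fertile from subfertile bulls, so the rule is a user decision:
#' either a quantile rule (the `ceiling(q * n)` lowest estimates are
#' subfertile) or a fixed threshold (estimates below it are subfertile).
#' Ties are broken deterministically by bull-id order.
#'
#' @param estimates data.frame from [estimate_bull_effects()] or a named
#'   numeric vector of estimates.
#' @param rule `"quantile"` or `"threshold"`.
#' @param q subfertile fraction for the quantile rule.
#' @param threshold cut value for the threshold rule.
#' @return data.frame `bull_id, estimate, fertility`.
#' @export
classify_fertility <- function(estimates, rule = c("quantile", "threshold"),
                               q = 0.43, threshold = 0) {
  rule <- match.arg(rule)
  if (is.data.frame(estimates)) {
    ids <- estimates$bull_id; est <- estimates$estimate
  } else {
    ids <- names(estimates) %||% as.character(seq_along(estimates))
    est <- as.numeric(estimates)
  }
  if (any(!is.finite(est))) stop("estimates must be finite")
  n <- length(est)
  fertility <- rep("fertile", n)
  if (rule == "quantile") {
    check_fraction(q, "q")
    k <- ceiling(q * n)
    ord <- order(est, ids)  # ties broken by bull id order
    fertility[ord[seq_len(k)]] <- "subfertile"
  } else {
    fertility[est < threshold] <- "subfertile"
  }
  data.frame(bull_id = ids, estimate = est, fertility = fertility,
             stringsAsFactors = FALSE)
}
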
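# Case-control association layer: burden collapsing, Firth penalized
# logistic regression with penalized-LRT p-values, the dosage-usage linear
# regression, and the Poisson detectability (power) calculator.

#' Collapse genotypes into a per-sample burden indicator
#'
#' Under the allelic model a sample is a carrier when it has genotype >= 1
#' for at least one member variant; under the recessive model when it is
#' homozygous alternate (genotype 2) for at least one member variant.
#' Missing genotypes are treated as non-carriers; the number imputed is
#' recorded.
#'
#' @param genotypes Integer dosage matrix (variants x samples, `NA` =
#'   missing), as returned by [parse_spliceai()].
#' @param variant_ids Row names to collapse; defaults to all rows.
#' @param model `"allelic"` or `"recessive"`.
#' @return Integer 0/1 vector over samples with attributes `model`,
#'   `n_variants`, `n_missing_imputed`.
#' @export
collapse_burden <- function(genotypes, variant_ids = NULL,
                            model = c("allelic", "recessive")) {
  model <- match.arg(model)
  if (is.null(variant_ids)) variant_ids <- rownames(genotypes)
  if (length(variant_ids) == 0L) stop("empty variant set")
  miss <- setdiff(variant_ids, rownames(genotypes))
  if (length(miss) > 0L) {
    stop("variant(s) absent from genotype matrix: ",
         paste(utils::head(miss, 3), collapse = ", "))
  }
  g <- genotypes[variant_ids, , drop = FALSE]
  n_missing <- sum(is.na(g))
  g[is.na(g)] <- 0L
  thr <- if (model == "allelic") 1L else 2L
  burden <- as.integer(apply(g >= thr, 2L, any))
  names(burden) <- colnames(genotypes)
  structure(burden, model = model, n_variants = length(variant_ids),
            n_missing_imputed = n_missing)
}

.firth_pll <- function(y, X, beta) {
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  W <- p * (1 - p)
  XW <- X * sqrt(W)
  info <- crossprod(XW)
  ll <- sum(y * stats::plogis(eta, log.p = TRUE) +
              (1 - y) * stats::plogis(-eta, log.p = TRUE))
  ll + 0.5 * as.numeric(determinant(info, logarithm = TRUE)$modulus)
}

#' Firth penalized logistic regression
#'
#' Maximizes the Jeffreys-penalized log-likelihood
#' \eqn{\ell^*(\beta) = \ell(\beta) + \frac12 \log\det I(\beta)} by Newton
#' iteration with step-halving, which yields finite estimates under complete
#' separation. All coefficients share the penalty. P-values come from
#' penalized likelihood-ratio tests: the model is refit with the coefficient
#' of interest fixed at zero (the penalty still evaluated on the full
#' design) and \eqn{2\,\Delta\ell^*} is referred to \eqn{\chi^2_1}.
#'
#' @param y Binary response vector (0/1).
#' @param X Design matrix including an intercept column.
#' @param fixed Optional named numeric vector of coefficients to hold fixed
#'   (used internally for the LRT refits).
#' @param max_iter Maximum Newton iterations (default 50).
#' @param score_tol Convergence on the max absolute penalized score
#'   (default 1e-6).
#' @param step_tol Convergence on the Newton step norm (default 1e-8).
#' @return For `firth_fit`: list with `coef`, `se`, `vcov`, `loglik_pen`,
#'   `iter`, `converged`. For `firth_logistic`: the same plus `p_lrt`, a
#'   named vector of penalized-LRT p-values per coefficient.
#' @export
firth_fit <- function(y, X, fixed = NULL, max_iter = 50L,
                      score_tol = 1e-6, step_tol = 1e-8) {
  X <- as.matrix(X)
  cn <- colnames(X)
  if (is.null(cn)) cn <- character(ncol(X))
  cn[!nzchar(cn)] <- paste0(".x", which(!nzchar(cn)))
  colnames(X) <- make.unique(cn)
  if (qr(X)$rank < ncol(X)) stop("design matrix is collinear")
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (!is.null(fixed)) {
    if (!all(names(fixed) %in% colnames(X))) stop("unknown fixed coefficient")
    beta[names(fixed)] <- fixed
  }
  free <- setdiff(colnames(X), names(fixed))
  if (length(free) == 0L) {
    return(list(coef = beta, se = rep(NA_real_, ncol(X)), vcov = NULL,
                loglik_pen = .firth_pll(y, X, beta), iter = 0L, converged = TRUE))
  }
  pll <- .firth_pll(y, X, beta)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p <- stats::plogis(drop(X %*% beta))
    W <- p * (1 - p)
    XW <- X * sqrt(W)
    info <- crossprod(XW)
    info_inv <- solve(info)
    h <- rowSums((XW %*% info_inv) * XW)
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    names(U) <- colnames(X)
    if (max(abs(U[free])) < score_tol) { converged <- TRUE; break }
    step <- drop(solve(info[free, free, drop = FALSE], U[free]))
    fac <- 1
    repeat {
      cand <- beta
      cand[free] <- cand[free] + fac * step
      pll_new <- .firth_pll(y, X, cand)
      if (is.finite(pll_new) && pll_new >= pll - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-10) break
    }
    if (sqrt(sum((fac * step)^2)) < step_tol) {
      beta <- cand; pll <- pll_new; converged <- TRUE; break
    }
    beta <- cand
    pll <- pll_new
    if (iter >= max_iter) break
  }
  if (!converged) {
    p <- stats::plogis(drop(X %*% beta))
    W <- p * (1 - p)
    XW <- X * sqrt(W)
    info <- crossprod(XW)
    h <- rowSums((XW %*% solve(info)) * XW)
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    stop(sprintf(
      "Firth regression did not converge in %d iterations (|score| = %.3g)",
      max_iter, max(abs(U[free]))))
  }
  p <- stats::plogis(drop(X %*% beta))
  W <- p * (1 - p)
  info <- crossprod(X * sqrt(W))
  vcov <- solve(info)
  list(coef = beta, se = sqrt(diag(vcov)), vcov = vcov,
       loglik_pen = pll, iter = iter, converged = TRUE)
}

#' @rdname firth_fit
#' @param test Coefficient names to test with the penalized LRT; defaults to
#'   all columns of `X`.
#' @export
firth_logistic <- function(y, X, test = NULL, max_iter = 50L,
                           score_tol = 1e-6, step_tol = 1e-8) {
  X <- as.matrix(X)
  cn <- colnames(X)
  if (is.null(cn)) cn <- character(ncol(X))
  cn[!nzchar(cn)] <- paste0(".x", which(!nzchar(cn)))
  colnames(X) <- make.unique(cn)
  fit <- firth_fit(y, X, max_iter = max_iter, score_tol = score_tol,
                   step_tol = step_tol)
  if (is.null(test)) test <- colnames(X)
  p_lrt <- stats::setNames(rep(NA_real_, length(test)), test)
  for (nm in test) {
    fit0 <- firth_fit(y, X, fixed = stats::setNames(0, nm),
                      max_iter = max_iter, score_tol = score_tol,
                      step_tol = step_tol)
    lr <- max(0, 2 * (fit$loglik_pen - fit0$loglik_pen))
    p_lrt[nm] <- stats::pchisq(lr, df = 1L, lower.tail = FALSE)
  }
  c(fit, list(p_lrt = p_lrt))
}

#' Test one collapsed unit for case-control association
#'
#' Fits `status ~ intercept + burden (+ covariates)` with Firth regression.
#' Units with fewer than `min_carriers` total carriers are skipped, not
#' tested (sparse-unit gating).
#'
#' @param burden 0/1 burden vector from [collapse_burden()].
#' @param status Binary phenotype vector aligned with `burden`.
#' @param covariates Optional numeric matrix/data.frame of covariates.
#' @param min_carriers Minimum total carriers required, default 3.
#' @param unit_id,unit_type Identifiers copied into the result row.
#' @return One-row `data.table`: `unit_id, unit_type, model, n_variants,
#'   n_carriers, n_case_carriers, n_control_carriers, beta, odds_ratio, se,
#'   p, skipped_reason`.
#' @export
test_unit <- function(burden, status, covariates = NULL, min_carriers = 3L,
                      unit_id = "unit", unit_type = "crsqtl") {
  if (length(burden) != length(status)) {
    stop("burden and phenotype vectors differ in length")
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(status)) {
      stop("covariate rows do not match phenotype length")
    }
  }
  n_case <- sum(burden == 1L & status == 1)
  n_ctrl <- sum(burden == 1L & status == 0)
  n_carriers <- n_case + n_ctrl
  base <- data.table::data.table(
    unit_id = unit_id, unit_type = unit_type,
    model = attr(burden, "model") %||% NA_character_,
    n_variants = attr(burden, "n_variants") %||% NA_integer_,
    n_carriers = n_carriers, n_case_carriers = n_case,
    n_control_carriers = n_ctrl,
    beta = NA_real_, odds_ratio = NA_real_, se = NA_real_, p = NA_real_,
    skipped_reason = NA_character_
  )
  if (n_carriers < min_carriers) {
    base$skipped_reason <- sprintf("carriers (%d) < min_carriers (%d)",
                                   n_carriers, min_carriers)
    return(base)
  }
  X <- cbind(`(Intercept)` = 1, burden = as.numeric(burden))
  if (!is.null(covariates)) X <- cbind(X, covariates)
  fit <- firth_logistic(status, X, test = "burden")
  base$beta <- unname(fit$coef["burden"])
  base$odds_ratio <- exp(base$beta)
  base$se <- unname(fit$se[which(colnames(X) == "burden")])
  base$p <- unname(fit$p_lrt["burden"])
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Association tests for every crsQTL
#'
#' @param crsqtls Membership table from [build_crsqtls()].
#' @param genotypes Dosage matrix (variants x samples).
#' @param status Binary phenotype aligned with the genotype columns.
#' @param covariates Optional covariate matrix.
#' @param model Genetic model for collapsing.
#' @param min_carriers Sparse-unit gate, default 3.
#' @return `data.table` with one row per crsQTL, including a
#'   Benjamini-Hochberg `p_bh` column (reported, never used for gating).
#' @export
crsqtl_tests <- function(crsqtls, genotypes, status, covariates = NULL,
                         model = c("allelic", "recessive"), min_carriers = 3L) {
  model <- match.arg(model)
  ids <- unique(crsqtls$junction_id)
  rows <- lapply(ids, function(jid) {
    vs <- unique(crsqtls$variant_id[crsqtls$junction_id == jid])
    b <- collapse_burden(genotypes, vs, model)
    test_unit(b, status, covariates, min_carriers, unit_id = jid,
              unit_type = "crsqtl")
  })
  out <- data.table::rbindlist(rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

#' SpliceAI-filtered gene burden test
#'
#' The comparison arm: collapses every rarity-filtered variant in a gene
#' whose maximum delta score reaches `delta_min` (regardless of junction
#' matching), then applies [test_unit()].
#'
#' @param variants Variant table (rarity-filtered).
#' @param predictions Prediction table (provides the gene assignment).
#' @param gene Gene identifier/symbol to test.
#' @param genotypes Dosage matrix.
#' @param status Binary phenotype.
#' @param covariates Optional covariates.
#' @param delta_min Qualifying score threshold, default 0.2.
#' @param model Genetic model.
#' @param min_carriers Sparse-unit gate, default 3.
#' @return One-row result as from [test_unit()] with `unit_type = "gene"`.
#' @export
gene_burden_test <- function(variants, predictions, gene, genotypes, status,
                             covariates = NULL, delta_min = 0.2,
                             model = c("allelic", "recessive"),
                             min_carriers = 3L) {
  model <- match.arg(model)
  in_gene <- unique(predictions$variant_id[predictions$gene == gene])
  vt <- variants[variants$variant_id %in% in_gene & variants$max_delta >= delta_min, ]
  if (nrow(vt) == 0L) {
    return(data.table::data.table(
      unit_id = gene, unit_type = "gene", model = model, n_variants = 0L,
      n_carriers = 0L, n_case_carriers = 0L, n_control_carriers = 0L,
      beta = NA_real_, odds_ratio = NA_real_, se = NA_real_, p = NA_real_,
      skipped_reason = "no qualifying variants"
    ))
  }
  b <- collapse_burden(genotypes, vt$variant_id, model)
  test_unit(b, status, covariates, min_carriers, unit_id = gene,
            unit_type = "gene")
}

#' Junction usage vs variant dosage linear regression
#'
#' Regresses per-sample junction usage (conventionally the -log10 outlier
#' p-value) on allele dosage (0/1/2) by ordinary least squares, optionally
#' with covariates, and reports the two-sided slope test.
#'
#' @param usage Numeric usage vector.
#' @param dosage Integer dosage vector in {0, 1, 2}.
#' @param covariates Optional covariate matrix.
#' @return List with `slope`, `se`, `p`, `n`.
#' @export
dosage_usage_regression <- function(usage, dosage, covariates = NULL) {
  if (length(usage) != length(dosage)) stop("usage and dosage lengths differ")
  if (length(unique(dosage)) < 2L) stop("dosage is constant; slope undefined")
  df <- data.frame(usage = usage, dosage = dosage)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- stats::lm(usage ~ ., data = df)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["dosage", "Estimate"]),
       se = unname(sm["dosage", "Std. Error"]),
       p = unname(sm["dosage", "Pr(>|t|)"]),
       n = length(usage))
}

#' Probability that a reference cohort detects a junction
#'
#' Assuming the number of expressing donors is Poisson with mean
#' `n_donors * junction_freq`, returns \eqn{P(X \ge 1) = 1 - e^{-np}}.
#'
#' @param junction_freq Expected proportion of donors expressing the
#'   junction, in [0, 1].
#' @param n_donors Reference cohort size (>= 0).
#' @return Detection probability, vectorized over both arguments.
#' @examples
#' detection_probability(0.001, 300)  # ~0.259
#' @export
detection_probability <- function(junction_freq, n_donors) {
  if (any(junction_freq < 0) || any(junction_freq > 1)) {
    stop("junction_freq must lie in [0, 1]")
  }
  if (any(n_donors < 0)) stop("n_donors must be non-negative")
  stats::ppois(0, lambda = n_donors * junction_freq, lower.tail = FALSE)
}
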
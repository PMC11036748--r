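#' Fit the glucocorticoid-integrated step-selection model
#'
#' Estimates selection coefficients by matched conditional logistic
#' regression: each stratum contributes one used step and `K` available
#' steps, and the likelihood conditions on exactly one choice per stratum,
#' \deqn{\sum_s [\beta^\top x_{used,s} - \log \sum_j \exp(\beta^\top x_{j,s})].}
#' Two equivalent estimation routes are provided. `"clogit"` maximizes the
#' conditional likelihood directly (via [survival::clogit()]; with one
#' case per stratum the partial likelihood is exactly the conditional
#' logistic likelihood). `"poisson_trick"` fits the log-link Poisson
#' reformulation with one free intercept per stratum; the habitat
#' coefficients of the two routes agree to numerical tolerance. Standard
#' errors come from the observed information; 95% confidence intervals are
#' Wald (`beta +/- 1.96 SE`) and are also reported on the `exp(beta)`
#' (relative selection) scale.
#'
#' @param design a [build_design()] table (or any data.frame with `used`,
#'   `stratum`, and the model columns).
#' @param mode `"clogit"` or `"poisson_trick"`.
#' @param terms character vector of design columns to include.
#' @return object of class `ssf_fit`: `coefficients`, `se`, `ci`
#'   (2-column matrix), `exp_coef`, `exp_ci`, `vcov`, `loglik`,
#'   `n_strata`, `K` (mean available:used ratio), `mode`, `converged`,
#'   plus the FGM scaling constants when present on the design.
#' @export
fit_ssf <- function(design,
                    mode = c("clogit", "poisson_trick"),
                    terms = c("dist_end", "dist_fgm", "dist_fgm_period",
                              "dist_fgm_days")) {
  mode <- match.arg(mode)
  miss <- setdiff(c(terms, "used", "stratum"), names(design))
  if (length(miss)) stopf("design lacks columns: %s", paste(miss, collapse = ", "))
  n_used <- tapply(design$used, design$stratum, sum)
  n_avail <- tapply(1 - design$used, design$stratum, sum)
  if (!all(n_used == 1) || !all(n_avail >= 1))
    stopf("every stratum needs exactly 1 used and >= 1 available step")
  X <- as.matrix(design[, terms, drop = FALSE])
  qrX <- qr(scale(X, scale = FALSE))
  if (qrX$rank < length(terms)) {
    bad <- terms[-qrX$pivot[seq_len(qrX$rank)]]
    stopf("singular design; collinear column(s): %s", paste(bad, collapse = ", "))
  }
  n_strata <- length(unique(design$stratum))

  if (mode == "clogit") {
    fml <- stats::reformulate(c(terms, "strata(stratum)"), response = "used")
    fit <- survival::clogit(fml, data = design)
    beta <- coef(fit)
    V <- as.matrix(vcov(fit))
    ll <- fit$loglik[2]
  } else {
    if (n_strata > 3000)
      stopf("poisson_trick with %d stratum intercepts exceeds the dense-GLM guard; use mode = 'clogit'", n_strata)
    design$.stratum_f <- factor(design$stratum)
    fml <- stats::reformulate(c("0", ".stratum_f", terms), response = "used")
    fit <- stats::glm(fml, family = stats::poisson(), data = design,
                      control = list(epsilon = 1e-12, maxit = 100))
    keep <- terms
    beta <- coef(fit)[keep]
    V <- as.matrix(vcov(fit))[keep, keep, drop = FALSE]
    ll <- as.numeric(logLik(fit))
  }
  converged <- all(is.finite(beta)) && all(abs(beta) < 15)
  se <- sqrt(diag(V))
  ci <- cbind(lower = beta - 1.96 * se, upper = beta + 1.96 * se)
  structure(
    list(coefficients = beta, se = se, ci = ci,
         exp_coef = exp(beta), exp_ci = exp(ci),
         vcov = V, loglik = ll, n_strata = n_strata,
         K = nrow(design) / n_strata - 1,
         mode = mode, converged = converged, terms = terms,
         fgm_scale = attr(design, "fgm_scale")),
    class = "ssf_fit")
}

#' @export
print.ssf_fit <- function(x, ...) {
  cat(sprintf("step-selection fit (%s), %d strata, K = %.0f%s\n",
              x$mode, x$n_strata, x$K,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(beta = x$coefficients, se = x$se,
                    `exp(beta)` = x$exp_coef,
                    lower95 = x$exp_ci[, 1], upper95 = x$exp_ci[, 2],
                    check.names = FALSE)
  print(round(tab, 4))
  invisible(x)
}

#' Sensitivity of coefficients to the available:used ratio
#'
#' Refits the model across a ladder of available:used ratios `K` to check
#' how many available steps are needed for stable coefficient estimates.
#' The availability draws are nested (common random numbers): one sample
#' of `max(ratios)` available steps is drawn per used step and each
#' smaller ratio uses its first `K` draws, so differences along the
#' ladder isolate the effect of the ratio itself rather than independent
#' resampling noise. The stability metric between two ratios is the
#' maximum over coefficients of `|beta(K1) - beta(K2)| / SE(K2)`.
#'
#' @param bouts a [make_bouts()] list.
#' @param landscape a [landscape_grid()].
#' @param ratios integer vector of ratios in `[1, 1000]`.
#' @param seed integer seed.
#' @param mode passed to [fit_ssf()].
#' @param terms passed to [fit_ssf()].
#' @param kernels optional [fit_kernels()]; fitted once from used steps if
#'   `NULL`.
#' @return data.frame of class `ratio_sensitivity`: one row per
#'   (`K`, `term`) with `beta` and `se`.
#' @seealso [stability_metric()]
#' @export
ratio_sensitivity <- function(bouts, landscape, ratios = c(1, 5, 10, 30, 40, 100),
                              seed = 1L, mode = "clogit",
                              terms = c("dist_end", "dist_fgm",
                                        "dist_fgm_period", "dist_fgm_days"),
                              kernels = NULL) {
  if (any(ratios < 1 | ratios > 1000)) stopf("ratios must lie in [1, 1000]")
  Kmax <- max(ratios)
  st <- build_strata(bouts, K = Kmax, landscape = landscape, kernels = kernels,
                     seed = child_seed(seed, "avail"))
  design <- build_design(st, landscape)
  # position of each available row within its stratum (1..Kmax, draw order)
  design <- design[order(design$stratum, -design$used), ]
  pos <- unlist(lapply(table(design$stratum), function(m) c(0L, seq_len(m - 1L))),
                use.names = FALSE)
  out <- lapply(sort(ratios), function(K) {
    fit <- fit_ssf(design[pos <= K, ], mode = mode, terms = terms)
    data.frame(K = K, term = names(fit$coefficients),
               beta = unname(fit$coefficients), se = unname(fit$se),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("ratio_sensitivity", "data.frame"))
}

#' @rdname ratio_sensitivity
#' @param tab a `ratio_sensitivity` table.
#' @param K1,K2 the two ratios to compare; `K2` supplies the reference SE.
#' @export
stability_metric <- function(tab, K1, K2 = max(tab$K)) {
  a <- tab[tab$K == K1, ]; b <- tab[tab$K == K2, ]
  a <- a[match(b$term, a$term), ]
  max(abs(a$beta - b$beta) / b$se)
}
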
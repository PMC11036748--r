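#' Standardize fecal glucocorticoid metabolite concentrations
#'
#' Centres and scales concentrations to mean 0, SD 1 (sample SD, i.e.
#' denominator n - 1) across the supplied samples. All model coefficients
#' involving FGMs in this package are per one SD of concentration; the
#' centring/scaling constants are kept as attributes so model predictions
#' can be mapped back to ug/g.
#'
#' @param x positive concentrations (ug/g), length >= 2.
#' @return numeric vector with attributes `mean` and `sd`.
#' @examples
#' z <- standardize_fgm(c(1200, 1900, 2600))
#' c(mean(z), sd(z))
#' @export
standardize_fgm <- function(x) {
  x <- as.numeric(x)
  if (sum(x > 0) < 2) stopf("need at least 2 samples with positive concentration")
  s <- sd(x)
  if (s == 0) stopf("concentrations have zero variance; cannot standardize")
  structure((x - mean(x)) / s, mean = mean(x), sd = s)
}

#' Specification of the pre/post-calving hormone model
#'
#' Settings for the hierarchical Gaussian model of standardized FGM
#' concentration on calving period (pre/post) and year, with random
#' intercepts per individual. MCMC settings follow the study protocol:
#' normal(0, 1) priors on slopes, 4 chains, 10,000 iterations of which
#' 5,000 are warmup.
#'
#' @param chains,iterations,warmup MCMC chain settings.
#' @param prior_slope_sd prior SD for fixed-effect slopes.
#' @return a list of class `prepost_spec`.
#' @export
prepost_spec <- function(chains = 4, iterations = 10000, warmup = 5000,
                         prior_slope_sd = 1) {
  if (warmup >= iterations) stopf("warmup must be < iterations")
  structure(list(chains = chains, iterations = iterations, warmup = warmup,
                 prior_slope_sd = prior_slope_sd), class = "prepost_spec")
}

#' Test for a pre/post-calving difference in glucocorticoid levels
#'
#' Fits standardized FGM concentration on calving period (post = deposited
#' on or after the calving date) and year, with a random intercept per
#' individual. Two engines are provided: `"likelihood"` fits a REML linear
#' mixed model ([lme4::lmer()]) and reports Wald 95% confidence intervals;
#' `"mcmc"` fits the Bayesian analogue by Gibbs sampling (JAGS) with
#' normal(0, `prior_slope_sd`) slope priors and reports posterior medians
#' with 95% quantile credible intervals. Samples from individual-years
#' with no calving record cannot be assigned a period and are dropped with
#' a message.
#'
#' @param samples data.frame of accepted samples: `individual_id` (or
#'   `assigned_individual`), `year`, `deposition_time`, `concentration`.
#' @param events data.frame: `individual_id`, `year`, `calving_date`
#'   (`Date`).
#' @param spec a [prepost_spec()].
#' @param engine `"likelihood"` or `"mcmc"`.
#' @param seed integer seed for the MCMC chains (per-chain RNG states are
#'   derived from it, making the sampler run-reproducible).
#' @return data.frame of class `effect_summary`: one row per fixed-effect
#'   term with `estimate`, `lo`, `hi` (95%), `engine`; the number of
#'   samples used is in attribute `n`.
#' @export
fit_prepost <- function(samples, events, spec = prepost_spec(),
                        engine = c("likelihood", "mcmc"), seed = 1L) {
  engine <- match.arg(engine)
  id <- samples$assigned_individual %||% samples$individual_id
  cd <- events$calving_date[match(paste(id, samples$year),
                                  paste(events$individual_id, events$year))]
  keep <- !is.na(cd)
  if (!all(keep))
    message(sum(!keep), " sample(s) without a calving record dropped from the pre/post model")
  if (sum(keep) < 3) stopf("too few samples with a matched calving period")
  d <- data.frame(
    individual = id[keep],
    post = as.integer(as.Date(samples$deposition_time[keep], tz = "UTC") >= cd[keep]),
    year = factor(samples$year[keep]),
    z = as.numeric(standardize_fgm(samples$concentration[keep])))
  if (length(unique(d$post)) < 2)
    stopf("all samples fall in a single period; the period effect is inestimable")
  use_year <- nlevels(d$year) > 1

  if (engine == "likelihood") {
    fml <- if (use_year) z ~ post + year + (1 | individual) else z ~ post + (1 | individual)
    fit <- lme4::lmer(fml, data = d, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    b <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    out <- data.frame(term = names(b), estimate = unname(b),
                      lo = unname(b - 1.96 * se), hi = unname(b + 1.96 * se),
                      engine = engine, stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("rjags", quietly = TRUE))
      stopf("the mcmc engine requires the rjags package")
    model_str <- paste0("model {
      for (i in 1:N) {
        mu[i] <- b0 + b_post * post[i]", if (use_year) " + b_year * yr[i]", " + u[ind[i]]
        y[i] ~ dnorm(mu[i], tau)
      }
      for (j in 1:J) { u[j] ~ dnorm(0, tau_u) }
      b0 ~ dnorm(0, ", 1 / spec$prior_slope_sd^2, ")
      b_post ~ dnorm(0, ", 1 / spec$prior_slope_sd^2, ")\n",
      if (use_year) paste0("b_year ~ dnorm(0, ", 1 / spec$prior_slope_sd^2, ")\n"),
      "sigma ~ dunif(0, 10); tau <- pow(sigma, -2)
      sigma_u ~ dunif(0, 10); tau_u <- pow(sigma_u, -2)
    }")
    dat <- list(y = d$z, post = d$post, ind = as.integer(factor(d$individual)),
                N = nrow(d), J = length(unique(d$individual)))
    if (use_year) dat$yr <- as.integer(d$year) - 1L
    mon <- c("b0", "b_post", if (use_year) "b_year")
    inits <- lapply(seq_len(spec$chains), function(ch)
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = child_seed(seed, ch)))
    jm <- rjags::jags.model(textConnection(model_str), data = dat,
                            inits = inits,
                            n.chains = spec$chains, quiet = TRUE)
    update(jm, spec$warmup, progress.bar = "none")
    sm <- rjags::coda.samples(jm, mon, n.iter = spec$iterations - spec$warmup,
                              progress.bar = "none")
    draws <- do.call(rbind, lapply(sm, as.matrix))
    qs <- apply(draws, 2, quantile, c(0.5, 0.025, 0.975))
    nm <- c(b0 = "(Intercept)", b_post = "post", b_year = "year")
    out <- data.frame(term = unname(nm[colnames(draws)]),
                      estimate = qs[1, ], lo = qs[2, ], hi = qs[3, ],
                      engine = engine, stringsAsFactors = FALSE)
    rownames(out) <- NULL
  }
  out$term[grepl("^year", out$term)] <- "year"
  structure(out, n = nrow(d), class = c("effect_summary", "data.frame"))
}
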
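#' Poisson composite log-likelihood of a joint SFS
#'
#' Treats unmasked entries as independent Poisson counts with mean
#' `alpha * M` where `M` is the model expectation and the scale `alpha`
#' (absorbing theta and the data size) is profiled analytically:
#' `alpha_hat = sum(D) / sum(M)`.  The returned value is
#' `sum(D * log(alpha_hat * M) - alpha_hat * M - lgamma(D + 1))`.
#'
#' @param observed A [joint_sfs()] of counts.
#' @param expectation A [joint_sfs()] (or matrix) of model expectations of
#'   the same shape.
#' @return The composite log-likelihood; `-Inf` (with a warning) if the
#'   expectation is zero where counts are observed.
#' @export
composite_loglik <- function(observed, expectation) {
  Mfull <- if (inherits(expectation, "ps_jsfs")) expectation$counts
           else as.matrix(expectation)
  if (!all(dim(Mfull) == dim(observed$counts)))
    stop("observed and expected spectra have different shapes")
  mask <- observed$mask
  if (inherits(expectation, "ps_jsfs")) mask <- mask | expectation$mask
  D <- observed$counts[!mask]
  M <- Mfull[!mask]
  if (sum(D) == 0) return(0)
  if (any(M <= 0 & D > 0)) {
    warning("expectation is zero at entries with observed counts")
    return(-Inf)
  }
  alpha <- sum(D) / sum(M)
  lam <- alpha * M
  terms <- -lam - lgamma(D + 1)
  pos <- D > 0
  terms[pos] <- terms[pos] + D[pos] * log(lam[pos])
  sum(terms)
}

#' Default optimization bounds
#'
#' Sizes are searched in `[1e-3, 1e2]` (relative to `Nref`), migration in
#' `[1e-2, 40]` (scaled `2*Nref*m`), and times in `[t_min, 20]` (units of
#' `2*Nref` generations).  The default `t_min = 0.01` keeps epochs above
#' roughly fifty thousand years at a reference size of order 2 million and
#' one generation per year.
#'
#' @param t_min Lower bound on epoch durations.
#' @return Named list of `c(lower, upper)` pairs keyed by parameter name
#'   prefix.
#' @export
default_bounds <- function(t_min = 0.01) {
  list(nu = c(1e-3, 1e2), M = c(1e-2, 40), t = c(t_min, 20),
       O = c(0.505, 0.999), P = c(1e-3, 0.999), nr = c(1e-3, 0.999),
       bf = c(1e-2, 1))
}

param_bounds <- function(names, bounds) {
  get1 <- function(nm) {
    if (startsWith(nm, "nu")) bounds$nu
    else if (startsWith(nm, "M")) bounds$M
    else if (startsWith(nm, "t_")) bounds$t
    else if (nm == "O") bounds$O
    else if (nm %in% c("P1", "P2")) bounds$P
    else if (nm == "nr") bounds$nr
    else if (nm == "bf") bounds$bf
    else stop("no bounds for parameter ", nm)
  }
  lo <- vapply(names, function(n) get1(n)[1], 0)
  hi <- vapply(names, function(n) get1(n)[2], 0)
  list(lo = lo, hi = hi)
}

# bounded <-> unconstrained transform (scaled logistic)
to_unconstrained <- function(v, lo, hi) {
  z <- pmin(pmax((v - lo) / (hi - lo), 1e-10), 1 - 1e-10)
  log(z / (1 - z))
}
to_bounded <- function(x, lo, hi) lo + (hi - lo) * (1 / (1 + exp(-x)))

#' Fit a demographic model to an observed joint SFS
#'
#' Maximizes the Poisson composite likelihood by derivative-free local
#' search (Nelder-Mead on logistic-transformed parameters) from multiple
#' random starts drawn log-uniformly within the bounds.  The best replicate
#' is retained and polished; all starts are recorded.
#'
#' @param observed A [joint_sfs()] of counts.
#' @param model_spec Scenario name (e.g. `"SC"`, `"PSC2N"`) or a list with
#'   elements `category` and `flags`.
#' @param n_starts Number of random starts.
#' @param seed Integer seed controlling starts (and the Monte-Carlo engine,
#'   if selected).
#' @param bounds See [default_bounds()].
#' @param engine,mc_loci,growth_steps Passed to [expected_sfs()].
#' @param init Optional named parameter vector used as an additional first
#'   start (with `n_starts = 0`, a single local search from `init`).
#' @param maxit Iteration cap per local search.
#' @param pad Exact-engine oversampling during the multi-start phase.
#' @param pad_polish Oversampling for the final polish of the best
#'   replicate (higher accuracy; the reported likelihood uses it).
#' @return Object of class `ps_fit`: fields `model` (name), `par`,
#'   `loglik`, `k`, `aic`, `starts` (per-start table), `convergence`.
#' @export
fit_model <- function(observed, model_spec, n_starts = 30, seed = NULL,
                      bounds = default_bounds(), engine = "exact",
                      mc_loci = 20000, growth_steps = 24, init = NULL,
                      maxit = 1000, pad = NULL, pad_polish = NULL) {
  if (is.null(pad)) pad <- max(0, 12 - max(observed$n1, observed$n2))
  if (is.null(pad_polish)) pad_polish <- pad + 4
  spec <- if (is.character(model_spec)) parse_model_name(model_spec)
          else model_spec
  pnames <- model_param_names(spec$category, spec$flags)
  b <- param_bounds(pnames, bounds)
  n1 <- observed$n1; n2 <- observed$n2

  make_objective <- function(pad_use) function(x) {
    v <- to_bounded(x, b$lo, b$hi)
    names(v) <- pnames
    if (all(c("P1", "P2") %in% pnames) && v["P1"] + v["P2"] > 1)
      return(1e9 * (1 + v["P1"] + v["P2"]))
    ll <- tryCatch({
      m <- demographic_model(spec$category, v, spec$flags)
      composite_loglik(observed,
                       expected_sfs(m, n1, n2, engine = engine,
                                    mc_loci = mc_loci, seed = 1,
                                    growth_steps = growth_steps,
                                    pad = pad_use))
    }, error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  objective <- make_objective(pad)

  starts <- with_seed(seed, {
    s <- list()
    if (!is.null(init))
      s[[1]] <- to_unconstrained(init[pnames], b$lo, b$hi)
    for (r in seq_len(n_starts)) {
      v <- exp(runif(length(pnames), log(b$lo), log(b$hi)))
      s[[length(s) + 1]] <- to_unconstrained(v, b$lo, b$hi)
    }
    s
  })
  if (length(starts) == 0) stop("no starts: give n_starts > 0 or init")

  runs <- lapply(starts, function(x0) {
    tryCatch(optim(x0, objective, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-10)),
             error = function(e) NULL)
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) stop("no start converged; check the observed SFS and bounds")
  vals <- vapply(runs, function(r) if (is.null(r)) Inf else r$value, 0)
  best <- which.min(vals)
  # polish the best replicate under a higher-accuracy engine configuration;
  # Nelder-Mead restarts (fresh simplex) until no further improvement, so
  # the returned optimum is a fixed point of refitting
  obj_polish <- make_objective(pad_polish)
  polish <- optim(runs[[best]]$par, obj_polish, method = "Nelder-Mead",
                  control = list(maxit = maxit, reltol = 1e-12))
  for (round in 1:4) {
    again <- optim(polish$par, obj_polish, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-12))
    if (polish$value - again$value < 1e-7) break
    polish <- again
  }
  par <- to_bounded(polish$par, b$lo, b$hi)
  names(par) <- pnames

  starts_tab <- data.frame(
    start = seq_along(runs),
    loglik = -vals,
    converged = vapply(runs, function(r)
      if (is.null(r)) FALSE else r$convergence == 0, logical(1)))
  k <- length(pnames)
  ll <- -polish$value
  structure(list(model = paste0(spec$category,
                                paste0(setdiff(spec$flags, "ex"), collapse = ""),
                                if ("ex" %in% spec$flags) "ex" else ""),
                 category = spec$category, flags = spec$flags,
                 par = par, loglik = ll, k = k, aic = 2 * k - 2 * ll,
                 starts = starts_tab, engine = engine,
                 convergence = polish$convergence, n1 = n1, n2 = n2),
            class = "ps_fit")
}

#' @export
print.ps_fit <- function(x, ...) {
  cat(sprintf("Model %s: lnL = %.4f, k = %d, AIC = %.4f\n",
              x$model, x$loglik, x$k, x$aic))
  print(round(x$par, 5))
  invisible(x)
}

#' Akaike information criterion
#'
#' `AIC = 2k - 2 lnL`.  Accepts a `ps_fit` or any list with elements
#' `loglik` and `k`.
#'
#' @param fit Fit object or `list(loglik =, k =)`.
#' @return The AIC value.
#' @export
aic <- function(fit) {
  stopifnot(!is.null(fit$loglik), !is.null(fit$k))
  2 * fit$k - 2 * fit$loglik
}

#' Rank fitted models by AIC
#'
#' @param fits List of `ps_fit` objects (or lists with `model`, `loglik`,
#'   `k`).
#' @return Data frame ordered by ascending AIC with a `dAIC` column.
#' @export
rank_models <- function(fits) {
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(model = f$model, k = f$k, loglik = f$loglik, AIC = aic(f),
               stringsAsFactors = FALSE)))
  tab <- tab[order(tab$AIC), , drop = FALSE]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  tab
}

star_band <- function(sd, estimate) {
  r <- abs(sd / estimate)
  ifelse(r <= 0.2, "", ifelse(r <= 0.5, "*", ifelse(r <= 1.5, "**", "***")))
}

#' Bootstrap uncertainty of a fitted model
#'
#' Refits every bootstrap replicate of the SFS by a local search started
#' from the best-fit parameters, and summarizes the spread of the replicate
#' estimates as per-parameter standard deviations with star-coded bands
#' (no star: SD below 20% of the estimate; `*`: 20-50%; `**`: 50-150%;
#' `***`: beyond).
#'
#' @param model_spec Scenario name or list, as in [fit_model()].
#' @param bootstrap_sfs_list Replicates from [bootstrap_sfs()].
#' @param best_fit The `ps_fit` to start each refit from.
#' @param ... Passed to [fit_model()].
#' @return List with `sd`, `bands`, `estimates` (replicates x parameters),
#'   `failed_fraction`, and logical `flag` set when more than 20% of
#'   replicate fits failed.
#' @export
bootstrap_uncertainty <- function(model_spec, bootstrap_sfs_list, best_fit,
                                  ...) {
  ests <- lapply(bootstrap_sfs_list, function(bs) {
    tryCatch(fit_model(bs, model_spec, n_starts = 0, init = best_fit$par,
                       ...)$par,
             error = function(e) NULL)
  })
  ok <- !vapply(ests, is.null, logical(1))
  failed <- mean(!ok)
  if (failed > 0.2)
    warning(sprintf("%.0f%% of bootstrap refits failed", 100 * failed))
  E <- do.call(rbind, ests[ok])
  sds <- apply(E, 2, sd)
  list(sd = sds, bands = star_band(sds, best_fit$par), estimates = E,
       failed_fraction = failed, flag = failed > 0.2)
}

#' Convert scaled parameters to demographic units
#'
#' Sizes become diploid individuals (`nu * Nref`), times become years
#' (`t * 2 * Nref * generation_time_years`), and migration rates become per
#' generation probabilities (`M / (2 * Nref)`).  Locus-class fractions and
#' `O` are returned unchanged.
#'
#' @param fit A `ps_fit` or named parameter vector.
#' @param Nref Reference (ancestral) diploid effective size, typically the
#'   harmonic mean of an external size reconstruction before the split.
#' @param generation_time_years Generation time in years.
#' @return Named numeric vector in demographic units.
#' @export
to_demographic_units <- function(fit, Nref, generation_time_years = 1) {
  par <- if (inherits(fit, "ps_fit")) fit$par else fit
  out <- numeric(0)
  for (nm in names(par)) {
    v <- unname(par[nm])
    if (startsWith(nm, "nu")) {
      out[sub("^nu_?", "N", nm)] <- v * Nref
    } else if (startsWith(nm, "t_")) {
      out[paste0("T", sub("^t_", "", nm), "_years")] <-
        v * 2 * Nref * generation_time_years
    } else if (startsWith(nm, "M")) {
      out[sub("^M", "m", nm)] <- v / (2 * Nref)
    } else {
      out[nm] <- v
    }
  }
  out
}

#' Serialize a fit as JSON
#' @param fit A `ps_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(model = fit$model, par = as.list(fit$par), loglik = fit$loglik,
         k = fit$k, aic = fit$aic),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
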
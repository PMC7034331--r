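#' Structural variants of the HIV evidence-synthesis model
#'
#' Two independent toggles alter how GUM-clinic data inform prevalence:
#'
#' * `undiagnosed_source`: `"gumcad_priors"` (base case) derives undiagnosed
#'   GMSM prevalence from the GUMCAD testing cascade plus strong prior
#'   assumptions about untested attenders, as the sum of an "unoffered" and an
#'   "opt-out" component; `"gum_anon_only"` (assumption (a)) replaces that
#'   construction with a flat Uniform(0, 1) prior so that undiagnosed
#'   prevalence is informed by the GUM Anon survey alone (GUMCAD still informs
#'   the cascade probabilities themselves).
#' * `gumcad_informs_diagnosed`: assumption (b); when `TRUE`, diagnosed GMSM
#'   prevalence is set directly from the cascade as
#'   `(1 - gamma1) + gamma1 gamma2 gamma3 gamma4` (probability of a previous
#'   plus a new diagnosis) instead of being inferred through the diagnosis
#'   registers.
#'
#' @param undiagnosed_source `"gumcad_priors"` or `"gum_anon_only"`.
#' @param gumcad_informs_diagnosed Logical.
#' @return An `hiv_variant` list.
#' @export
hiv_variant <- function(undiagnosed_source = c("gumcad_priors", "gum_anon_only"),
                        gumcad_informs_diagnosed = FALSE) {
  structure(
    list(
      undiagnosed_source = arg_match(undiagnosed_source),
      gumcad_informs_diagnosed = isTRUE(gumcad_informs_diagnosed)
    ),
    class = "hiv_variant"
  )
}

#' @export
print.hiv_variant <- function(x, ...) {
  cat("<hiv_variant>", x$undiagnosed_source,
      if (x$gumcad_informs_diagnosed) "+ GUMCAD informs diagnosed prevalence",
      "\n")
  invisible(x)
}

#' Founder parameters of the HIV model
#'
#' Returns the names of the founder nodes (parameters with no parents in the
#' model graph) under a given variant, in the column order used by
#' [derived_outputs()] and [log_posterior()].
#'
#' @param variant An [hiv_variant()].
#' @return Character vector of founder column names.
#' @export
hiv_founder_names <- function(variant = hiv_variant()) {
  stopifnot(inherits(variant, "hiv_variant"))
  base <- c(
    "log_mu_pop", "rho_G", "rho_N", "rho_P",
    "a_S", "a_H", "a_delta_G", "a_delta_N", "a_delta_P",
    "gamma1", "gamma2", "gamma3", "gamma4",
    "a_UN", "a_OP", "p_G_GM", "p_N_GM", "u_P"
  )
  if (variant$undiagnosed_source == "gum_anon_only") c(base, "pibar_G_free") else base
}

# support bounds of each founder; gamma4 upper bound and a_UN bounds are the
# substantive prior constraints
hiv_founder_support <- function(variant = hiv_variant()) {
  sup <- list(
    log_mu_pop = c(-Inf, Inf),
    rho_G = c(0, 1), rho_N = c(0, 1), rho_P = c(0, 1),
    a_S = c(-Inf, Inf), a_H = c(0, 1),
    a_delta_G = c(0, 1), a_delta_N = c(0, 1), a_delta_P = c(0, 1),
    gamma1 = c(0, 1), gamma2 = c(0, 1), gamma3 = c(0, 1), gamma4 = c(0, 0.15),
    a_UN = c(log(0.5), log(1.5)), a_OP = c(0, 1),
    p_G_GM = c(0, 1), p_N_GM = c(0, 1), u_P = c(0, 1)
  )
  if (variant$undiagnosed_source == "gum_anon_only") sup$pibar_G_free <- c(0, 1)
  sup
}

#' Check founder draws against the prior support
#'
#' @param founders Data frame of founder values (one row per draw).
#' @param variant An [hiv_variant()].
#' @return Logical vector, one entry per row.
#' @export
hiv_in_support <- function(founders, variant = hiv_variant()) {
  sup <- hiv_founder_support(variant)
  ok <- rep(TRUE, nrow(founders))
  for (nm in names(sup)) {
    v <- founders[[nm]]
    ok <- ok & is.finite(v) & v > sup[[nm]][1] & v < sup[[nm]][2]
  }
  ok & (founders$rho_G + founders$rho_N + founders$rho_P < 1)
}

#' Deterministic outputs of the HIV model graph
#'
#' Propagates founder values through the deterministic part of the model graph
#' to every derived quantity: subgroup sizes, diagnosed and undiagnosed
#' prevalences, the testing-cascade decomposition of undiagnosed GMSM
#' prevalence, the GUM Anon and GMSHS link functions, and all case counts.
#'
#' @param founders Data frame with one row per draw and the columns named by
#'   [hiv_founder_names()].
#' @param variant An [hiv_variant()].
#' @return A tibble with one row per input row and all output columns
#'   (`mu_pop`, `r_*`, `pibar_*`, `pidelta_*`, `pi_*`, `delta_*`, `mu_D*`,
#'   `mu_U*`, `mu_D`, `mu_M`, `p_H`, `pi_UN`, `pi_OP`, `p_UN`, `a_EX`,
#'   `pi_GD`, `pi_GA`, `or_GM`, `mu_U_2grp`, `mu_U_3grp`, `mu`).
#' @export
derived_outputs <- function(founders, variant = hiv_variant()) {
  stopifnot(inherits(variant, "hiv_variant"))
  founders <- as_tibble(founders)
  need <- hiv_founder_names(variant)
  missing_cols <- setdiff(need, names(founders))
  if (length(missing_cols)) {
    abort(sprintf("Missing founder columns: %s", paste(missing_cols, collapse = ", ")))
  }
  if (!all(hiv_in_support(founders, variant))) {
    abort("Founder values outside the prior support.")
  }
  f <- founders
  odds <- function(p) p / (1 - p)
  inv_odds <- function(o) o / (1 + o)

  out <- tibble(.rows = nrow(f))
  out$mu_pop <- exp(f$log_mu_pop)
  out$r_G <- f$rho_G * out$mu_pop
  out$r_N <- f$rho_N * out$mu_pop
  out$r_P <- f$rho_P * out$mu_pop

  # GUMCAD cascade decomposition of undiagnosed GMSM prevalence
  out$pi_GD <- f$gamma1 * f$gamma2 * f$gamma3 * f$gamma4
  out$p_UN <- plogis(qlogis(f$gamma4) + f$a_UN)
  out$a_EX <- f$a_OP * (0.15 - f$gamma4)
  out$pi_UN <- f$gamma1 * (1 - f$gamma2) * out$p_UN
  out$pi_OP <- f$gamma1 * f$gamma2 * (1 - f$gamma3) * (f$gamma4 + out$a_EX)

  out$pibar_G <- if (variant$undiagnosed_source == "gum_anon_only") {
    f$pibar_G_free
  } else {
    out$pi_UN + out$pi_OP
  }
  out$pi_GA <- (out$pibar_G + out$pi_GD) / f$gamma1

  # GMSHS odds-ratio link from GMSM to NGMSM undiagnosed prevalence
  out$or_GM <- odds(f$p_N_GM) / odds(f$p_G_GM)
  out$pibar_N <- inv_odds(odds(out$pibar_G) * out$or_GM)
  out$pibar_P <- f$u_P * out$pibar_N

  # diagnosed fractions via the constraint delta_g < 1 - pibar_g
  out$delta_G <- f$a_delta_G * (1 - out$pibar_G)
  out$delta_N <- f$a_delta_N * (1 - out$pibar_N)
  out$delta_P <- f$a_delta_P * (1 - out$pibar_P)
  out$pi_G <- out$pibar_G / (1 - out$delta_G)
  out$pi_N <- out$pibar_N / (1 - out$delta_N)
  out$pi_P <- out$pibar_P / (1 - out$delta_P)
  out$pidelta_G <- out$pi_G * out$delta_G
  out$pidelta_N <- out$pi_N * out$delta_N
  out$pidelta_P <- out$pi_P * out$delta_P

  if (variant$gumcad_informs_diagnosed) {
    out$pidelta_G <- (1 - f$gamma1) + f$gamma1 * f$gamma2 * f$gamma3 * f$gamma4
    out$pi_G <- out$pibar_G + out$pidelta_G
    out$delta_G <- out$pidelta_G / out$pi_G
  }

  out$mu_DG <- out$mu_pop * f$rho_G * out$pidelta_G
  out$mu_DN <- out$mu_pop * f$rho_N * out$pidelta_N
  out$mu_DP <- out$mu_pop * f$rho_P * out$pidelta_P
  out$mu_UG <- out$mu_pop * f$rho_G * out$pibar_G
  out$mu_UN <- out$mu_pop * f$rho_N * out$pibar_N
  out$mu_UP <- out$mu_pop * f$rho_P * out$pibar_P
  out$mu_D <- out$mu_DG + out$mu_DN + out$mu_DP
  out$mu_M <- exp(f$a_S) * out$mu_D
  out$p_H <- f$a_H * out$mu_DG / out$mu_D
  out$mu_U_2grp <- out$mu_UG + out$mu_UN
  out$mu_U_3grp <- out$mu_UG + out$mu_UN + out$mu_UP
  out$mu <- out$mu_DG + out$mu_DN + out$mu_UG + out$mu_UN

  prev_cols <- c(
    "pibar_G", "pibar_N", "pibar_P", "pidelta_G", "pidelta_N", "pidelta_P",
    "pi_G", "pi_N", "pi_P", "delta_G", "delta_N", "delta_P", "pi_GD",
    "pi_UN", "pi_OP", "p_UN", "p_H"
  )
  bad <- vapply(out[prev_cols], function(v) any(v < 0 | v > 1), TRUE)
  if (any(bad)) {
    abort(sprintf(
      "Derived prevalence outside [0, 1] (support violation): %s",
      paste(prev_cols[bad], collapse = ", ")
    ))
  }
  out
}

#' Log posterior density of the HIV model
#'
#' Sum of the founder log priors and the log likelihood of every active data
#' source, up to an additive constant that does not depend on the parameters.
#' Returns `-Inf` outside the support. Primarily a verification surface: the
#' sampler itself runs in JAGS, and this function provides an independent
#' density to check it against.
#'
#' @param founders One draw: a named numeric vector or a one-row data frame of
#'   founder values.
#' @param data An [hiv_observations()] list.
#' @param variant An [hiv_variant()].
#' @param sources Character subset of
#'   `c("pop", "natsal", "gumcad", "gum_anon", "sophid", "handd", "gmshs")`
#'   naming the likelihood terms to include. Empty vector gives the prior
#'   density alone.
#' @return A single log density value.
#' @export
log_posterior <- function(founders, data = hiv_observations(),
                          variant = hiv_variant(),
                          sources = hiv_sources()) {
  stopifnot(inherits(data, "hiv_observations"))
  sources <- match_sources(sources)
  if (is.numeric(founders)) founders <- as_tibble(as.list(founders))
  founders <- as_tibble(founders)
  stopifnot(nrow(founders) == 1)
  if (!hiv_in_support(founders, variant)) return(-Inf)

  f <- founders
  lp <- dnorm(f$log_mu_pop, 0, 1000, log = TRUE)
  lp <- lp + lgamma(4)  # uniform Dirichlet density on the 4-simplex
  # reporting bias: exp(a_S) ~ N(1, 0.018^2), with Jacobian of the log transform
  lp <- lp + dnorm(exp(f$a_S), 1, 0.018, log = TRUE) + f$a_S
  lp <- lp + dunif(f$gamma4, 0, 0.15, log = TRUE)
  lp <- lp + dunif(f$a_UN, log(0.5), log(1.5), log = TRUE)
  # remaining founders are U(0,1): zero contribution on the support

  # prevalences outside [0,1] (possible when free undiagnosed prevalence and
  # the cascade-based diagnosed prevalence combine) have zero posterior density
  out <- tryCatch(derived_outputs(f, variant), error = function(e) NULL)
  if (is.null(out)) return(-Inf)
  d <- data
  if ("pop" %in% sources) lp <- lp + dpois(d$ypop, out$mu_pop, log = TRUE)
  if ("natsal" %in% sources) {
    counts <- c(d$y_G, d$y_N, d$y_P, d$y_NAT - d$y_G - d$y_N - d$y_P)
    probs <- c(f$rho_G, f$rho_N, f$rho_P, 1 - f$rho_G - f$rho_N - f$rho_P)
    lp <- lp + dmultinom(counts, prob = probs, log = TRUE)
  }
  if ("gumcad" %in% sources) {
    lp <- lp + dbinom(d$g2, d$g1, f$gamma1, log = TRUE) +
      dbinom(d$g3, d$g2, f$gamma2, log = TRUE) +
      dbinom(d$g4, d$g3, f$gamma3, log = TRUE) +
      dbinom(d$g5, d$g4, f$gamma4, log = TRUE)
  }
  if ("gum_anon" %in% sources) {
    if (out$pi_GA >= 1) return(-Inf)
    lp <- lp + dbinom(d$g_A, d$g_AN, out$pi_GA, log = TRUE)
  }
  if ("sophid" %in% sources) lp <- lp + dpois(d$y_M, out$mu_M, log = TRUE)
  if ("handd" %in% sources) lp <- lp + dbinom(d$y_H, d$y_M, out$p_H, log = TRUE)
  if ("gmshs" %in% sources) {
    lp <- lp + dbinom(d$y_G_GM, d$n_G_GM, f$p_G_GM, log = TRUE) +
      dbinom(d$y_N_GM, d$n_N_GM, f$p_N_GM, log = TRUE)
  }
  as.numeric(lp)
}

#' @rdname log_posterior
#' @export
hiv_sources <- function() {
  c("pop", "natsal", "gumcad", "gum_anon", "sophid", "handd", "gmshs")
}

match_sources <- function(sources) {
  if (length(sources) == 0) return(character(0))
  bad <- setdiff(sources, hiv_sources())
  if (length(bad)) abort(sprintf("Unknown data sources: %s", paste(bad, collapse = ", ")))
  sources
}
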
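syndrome_levels <- c("asymptomatic", "mild_swelling",
                     "painful_progressive_swelling", "venom_ophthalmia",
                     "progressive_weakness", "bleeding")

#' Syndromes counted as cytotoxic envenoming
#'
#' Mild swelling, painful progressive swelling and venom ophthalmia.
#' @export
cytotoxic_syndromes <- c("mild_swelling", "painful_progressive_swelling",
                         "venom_ophthalmia")

#' Validate a case registry
#'
#' Applies the record invariants (hour in 0-23, age >= 0, syndrome from
#' the closed vocabulary, antivenom fields only when antivenom was
#' received) and splits the input into accepted and rejected rows with
#' reasons.
#'
#' @param registry data.frame of case records, or a path to a CSV with the
#'   registry column layout.
#' @return list: `accepted` (data.frame), `rejected` (data.frame with a
#'   `reason` column), `n_accepted`, `n_rejected`.
#' @export
validate_registry <- function(registry) {
  if (is.character(registry)) {
    if (!file.exists(registry)) stop("cannot read registry: ", registry)
    registry <- utils::read.csv(registry, stringsAsFactors = FALSE)
  }
  n <- nrow(registry)
  reason <- rep(NA_character_, n)
  flag <- function(bad, why) {
    bad <- which(bad & is.na(reason))
    reason[bad] <<- why
  }
  if ("hour" %in% names(registry))
    flag(!is.na(registry$hour) &
           (registry$hour < 0 | registry$hour > 23), "hour out of range")
  if ("age" %in% names(registry))
    flag(!is.na(registry$age) & registry$age < 0, "negative age")
  if ("syndrome" %in% names(registry))
    flag(!is.na(registry$syndrome) &
           !(registry$syndrome %in% syndrome_levels),
         "syndrome outside closed vocabulary")
  if (all(c("vials", "antivenom") %in% names(registry)))
    flag(!is.na(registry$vials) & !registry$antivenom,
         "vials recorded without antivenom")
  if ("vials" %in% names(registry))
    flag(!is.na(registry$vials) &
           (registry$vials < 1 | registry$vials > 25),
         "vials out of range")
  ok <- is.na(reason)
  rejected <- registry[!ok, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!ok]
  list(accepted = registry[ok, , drop = FALSE], rejected = rejected,
       n_accepted = sum(ok), n_rejected = sum(!ok))
}

#' Tabulate a registry dimension
#'
#' Counts and percentages of all records for one categorical dimension;
#' missing values appear as their own "not recorded" category.
#'
#' @param cases case registry data.frame.
#' @param dimension one of month, hour, age_band, sex, occupation,
#'   location, bite_site, activity, syndrome, outcome.
#' @param digits rounding of the percentage column (default 1, matching a
#'   one-decimal reporting table).
#' @return data.frame: `category`, `n`, `pct`.
#' @export
tabulate_cases <- function(cases, dimension, digits = 1) {
  dims <- c("month", "hour", "age_band", "sex", "occupation", "location",
            "bite_site", "activity", "syndrome", "outcome")
  if (!dimension %in% dims)
    stop("unknown dimension '", dimension, "'; use one of: ",
         paste(dims, collapse = ", "))
  if (nrow(cases) == 0L) stop("registry is empty")
  v <- as.character(cases[[dimension]])
  v[is.na(v)] <- "not recorded"
  tt <- table(v)
  out <- data.frame(category = names(tt), n = as.integer(tt))
  out$pct <- round(100 * out$n / nrow(cases), digits)
  out[order(-out$n), , drop = FALSE]
}

#' Annual average number of cases
#'
#' @param cases case registry data.frame (or an integer count).
#' @param period_years observation period in years (> 0).
#' @return cases per year.
#' @export
annual_average <- function(cases, period_years) {
  if (period_years <= 0) stop("period_years must be positive")
  n <- if (is.data.frame(cases)) nrow(cases) else as.numeric(cases)
  n / period_years
}

#' Relative risk with 95% confidence interval
#'
#' `RR = (cases_a / pop_a) / (cases_b / pop_b)` with the log-scale CI
#' `exp(log RR +/- 1.96 sqrt(1/cases_a - 1/pop_a + 1/cases_b - 1/pop_b))`
#' using census population denominators.
#'
#' @param cases_a,pop_a cases and population of group a.
#' @param cases_b,pop_b cases and population of group b.
#' @return data.frame: `rr`, `lower`, `upper`, `ci_defined`.
#' @export
relative_risk <- function(cases_a, pop_a, cases_b, pop_b) {
  if (pop_a < cases_a || pop_b < cases_b)
    stop("population must be at least the case count")
  rr <- (cases_a / pop_a) / (cases_b / pop_b)
  if (cases_a == 0 || cases_b == 0)
    return(data.frame(rr = rr, lower = NA_real_, upper = NA_real_,
                      ci_defined = FALSE))
  se <- sqrt(1 / cases_a - 1 / pop_a + 1 / cases_b - 1 / pop_b)
  data.frame(rr = rr, lower = exp(log(rr) - 1.96 * se),
             upper = exp(log(rr) + 1.96 * se), ci_defined = TRUE)
}

#' Chi-squared test of independence with Cramer's V
#'
#' Pearson chi-squared on a contingency table with
#' `df = (r - 1)(c - 1)` and the effect size
#' `V = sqrt(chi2 / (n (min(r, c) - 1)))`, in `[0, 1]`.
#'
#' @param tab non-negative integer matrix, at least 2 x 2.
#' @return data.frame: `chi2`, `df`, `cramers_v`, `n`.
#' @export
chi2_cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("table must be at least 2x2")
  if (any(tab < 0)) stop("table entries must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal row/column")
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  v <- sqrt(chi2 / (n * (min(dim(tab)) - 1L)))
  data.frame(chi2 = chi2, df = df, cramers_v = v, n = n)
}

#' Log-linear elevation-incidence rate fit
#'
#' Poisson log-linear model fitted by iteratively reweighted least
#' squares: `log rate = alpha + beta * (elevation / 100 m)` with
#' `log(population x years)` offset. Returns the coefficient per 100 m,
#' its standard error from the observed information matrix, and the
#' percent change per 100 m, `100 (1 - exp(beta))`, with its delta-method
#' standard error. (A Poisson fit stands in for a negative-binomial one;
#' the rate coefficient is the quantity of interest and the synthetic
#' generator is Poisson.)
#'
#' @param counts per-EA case counts (>= 0), at least 10 EAs.
#' @param elevation per-EA mean elevation in metres.
#' @param offset_population per-EA person-years of exposure
#'   (population x period).
#' @param tol convergence tolerance on the coefficient change.
#' @param max_iter iteration cap (error on non-convergence).
#' @return data.frame: `coef_per_100m`, `se`, `percent_change_per_100m`,
#'   `percent_change_se`, `iterations`.
#' @export
poisson_elevation_fit <- function(counts, elevation, offset_population,
                                  tol = 1e-8, max_iter = 50L) {
  if (length(counts) < 10L) stop("need at least 10 EAs")
  if (any(counts < 0)) stop("counts must be non-negative")
  x <- elevation / 100
  X <- cbind(1, x)
  off <- log(offset_population)
  beta <- c(log(max(sum(counts), 1) / sum(offset_population)), 0)
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) stop("IRLS did not converge in ", max_iter,
                            " iterations")
    eta <- drop(X %*% beta) + off
    mu <- exp(eta)
    W <- mu
    z <- (eta - off) + (counts - mu) / mu
    XtWX <- crossprod(X, X * W)
    XtWz <- crossprod(X, W * z)
    beta_new <- drop(solve(XtWX, XtWz))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  mu <- exp(drop(X %*% beta) + off)
  info <- crossprod(X, X * mu)
  se <- sqrt(diag(solve(info)))[2]
  b <- beta[2]
  data.frame(coef_per_100m = b, se = se,
             percent_change_per_100m = 100 * (1 - exp(b)),
             percent_change_se = 100 * exp(b) * se,
             iterations = it)
}
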
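# Site-class model catalogue: M0, M1a, M2a, M7, M8, branch-site A (+ null).

#' Discretize a beta distribution into equal-weight omega categories
#'
#' Splits Beta(p, q) into `K` equal-probability bins and represents each bin
#' by its conditional median, i.e. the (k - 1/2)/K quantile.  Used to realize
#' the purifying-selection site distributions of models M7 and M8.
#'
#' @param p,q Beta shape parameters (> 0).
#' @param K Number of categories (>= 1).
#' @return Data frame with columns `omega` (in (0,1)) and `weight` (= 1/K).
#' @export
discretize_beta <- function(p, q, K) {
  if (!is.numeric(K) || K < 1) stop("K must be >= 1")
  if (p <= 0 || q <= 0) stop("beta shapes must be positive")
  K <- as.integer(K)
  omega <- stats::qbeta((seq_len(K) - 0.5) / K, p, q)
  # keep omegas strictly inside (0,1) for numerical sanity
  omega <- pmin(pmax(omega, 1e-8), 1 - 1e-8)
  data.frame(omega = omega, weight = rep(1 / K, K))
}

#' Construct a realized site-class model
#'
#' A site-class model assigns every alignment site to one of a few omega
#' classes; branch-site classes additionally distinguish foreground from
#' background branches.  Supported models:
#' \describe{
#'   \item{M0}{one class, free `omega`.}
#'   \item{M1a}{nearly-neutral: classes (omega0 in (0,1), 1) with weights
#'     (p0, 1 - p0).}
#'   \item{M2a}{positive selection: adds a class omega2 >= 1 with weight
#'     1 - p0 - p1.}
#'   \item{M7}{Beta(p, q) purifying distribution in `K` categories.}
#'   \item{M8}{M7 plus a class at omega_s >= 1 with weight 1 - p0.}
#'   \item{branch_site_A}{four classes; background omegas (omega0, 1, omega0,
#'     1), foreground omegas (omega0, 1, omega2, omega2) with omega2 >= 1;
#'     weights (p0, p1, p2*p0/(p0+p1), p2*p1/(p0+p1)) with p2 = 1 - p0 - p1.}
#'   \item{branch_site_A_null}{branch-site A with omega2 fixed at 1.}
#' }
#'
#' @param name Model name (one of the above).
#' @param omega,omega0,omega2,omega_s,p0,p1,p,q Model parameters as described.
#' @param K Number of beta categories for M7/M8.
#' @return Object of class `site_class_model`: list with `name`, `omega_bg`,
#'   `omega_fg` (NULL unless branch-site), `weights`, `params` (the free
#'   parameters as a named list), and `needs_foreground`.
#' @export
site_class_model <- function(name, omega = NULL, omega0 = NULL, omega2 = NULL,
                             omega_s = NULL, p0 = NULL, p1 = NULL,
                             p = NULL, q = NULL, K = 10) {
  name <- match.arg(name, c("M0", "M1a", "M2a", "M7", "M8",
                            "branch_site_A", "branch_site_A_null"))
  chk01 <- function(x, what) {
    if (is.null(x) || x <= 0 || x >= 1) stop(what, " must lie in (0,1)")
    x
  }
  chkpos <- function(x, what) {
    if (is.null(x) || x < 0) stop(what, " must be nonnegative")
    x
  }
  out <- switch(name,
    M0 = {
      list(omega_bg = chkpos(omega, "omega"), omega_fg = NULL, weights = 1,
           params = list(omega = omega))
    },
    M1a = {
      list(omega_bg = c(chk01(omega0, "omega0"), 1),
           omega_fg = NULL,
           weights = c(chk01(p0, "p0"), 1 - p0),
           params = list(p0 = p0, omega0 = omega0))
    },
    M2a = {
      if (is.null(omega2) || omega2 < 1) stop("omega2 must be >= 1")
      if (is.null(p1) || p1 < 0 || p0 + p1 >= 1) {
        stop("need p0, p1 >= 0 with p0 + p1 < 1")
      }
      list(omega_bg = c(chk01(omega0, "omega0"), 1, omega2),
           omega_fg = NULL,
           weights = c(p0, p1, 1 - p0 - p1),
           params = list(p0 = p0, p1 = p1, omega0 = omega0, omega2 = omega2))
    },
    M7 = {
      db <- discretize_beta(chkpos(p, "p"), chkpos(q, "q"), K)
      list(omega_bg = db$omega, omega_fg = NULL, weights = db$weight,
           params = list(p = p, q = q), beta_params = c(p, q))
    },
    M8 = {
      if (is.null(omega_s) || omega_s < 1) stop("omega_s must be >= 1")
      db <- discretize_beta(chkpos(p, "p"), chkpos(q, "q"), K)
      list(omega_bg = c(db$omega, omega_s),
           omega_fg = NULL,
           weights = c(chk01(p0, "p0") * db$weight, 1 - p0),
           params = list(p0 = p0, p = p, q = q, omega_s = omega_s),
           beta_params = c(p, q))
    },
    branch_site_A = ,
    branch_site_A_null = {
      if (name == "branch_site_A_null") omega2 <- 1
      if (is.null(omega2) || omega2 < 1) stop("omega2 must be >= 1")
      if (is.null(p1) || p1 < 0 || p0 + p1 >= 1) {
        stop("need p0, p1 >= 0 with p0 + p1 < 1")
      }
      chk01(omega0, "omega0")
      p2 <- 1 - p0 - p1
      w <- c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1))
      list(omega_bg = c(omega0, 1, omega0, 1),
           omega_fg = c(omega0, 1, omega2, omega2),
           weights = w,
           params = list(p0 = p0, p1 = p1, omega0 = omega0, omega2 = omega2))
    }
  )
  out$name <- name
  out$n_beta_categories <- if (name %in% c("M7", "M8")) as.integer(K) else NULL
  out$needs_foreground <- grepl("^branch_site", name)
  stopifnot(abs(sum(out$weights) - 1) < 1e-9, all(out$weights >= 0))
  class(out) <- "site_class_model"
  out
}

#' @export
print.site_class_model <- function(x, ...) {
  cat("Site-class model", x$name, "\n")
  tab <- data.frame(omega_bg = x$omega_bg,
                    omega_fg = x$omega_fg %||% x$omega_bg,
                    weight = x$weights)
  print(tab, row.names = FALSE)
  invisible(x)
}

# ---- free-parameter packing for the optimizer --------------------------

# Each model's free parameters are mapped to an unconstrained vector:
#   log        for omega (M0), p, q
#   logit      for omega0, p0 (and p1 via stick-breaking)
#   log(x - 1) for omega2 / omega_s (lower bound 1)
logit <- function(x) log(x / (1 - x))
inv_logit <- function(x) 1 / (1 + exp(-x))

model_par_info <- function(name, omega_max = 50) {
  switch(name,
    M0 = list(names = "omega", lower = log(1e-6), upper = log(omega_max)),
    M1a = list(names = c("p0", "omega0"),
               lower = c(-10, -12), upper = c(10, 10)),
    M2a = list(names = c("p0", "p1", "omega0", "omega2"),
               lower = c(-10, -10, -12, log(1e-6)),
               upper = c(10, 10, 10, log(omega_max - 1))),
    M7 = list(names = c("p", "q"), lower = rep(log(5e-3), 2),
              upper = rep(log(99), 2)),
    M8 = list(names = c("p0", "p", "q", "omega_s"),
              lower = c(-10, rep(log(5e-3), 2), log(1e-6)),
              upper = c(10, rep(log(99), 2), log(omega_max - 1))),
    branch_site_A = list(names = c("p0", "p1", "omega0", "omega2"),
                         lower = c(-10, -10, -12, log(1e-6)),
                         upper = c(10, 10, 10, log(omega_max - 1))),
    branch_site_A_null = list(names = c("p0", "p1", "omega0"),
                              lower = c(-10, -10, -12),
                              upper = c(10, 10, 10)),
    stop("unknown model: ", name)
  )
}

# natural parameters -> transformed optimizer vector
model_par_pack <- function(name, par) {
  switch(name,
    M0 = log(par$omega),
    M1a = c(logit(par$p0), logit(par$omega0)),
    M2a = c(logit(par$p0), logit(par$p1 / (1 - par$p0)),
            logit(par$omega0), log(par$omega2 - 1 + 1e-9)),
    M7 = c(log(par$p), log(par$q)),
    M8 = c(logit(par$p0), log(par$p), log(par$q),
           log(par$omega_s - 1 + 1e-9)),
    branch_site_A = c(logit(par$p0), logit(par$p1 / (1 - par$p0)),
                      logit(par$omega0), log(par$omega2 - 1 + 1e-9)),
    branch_site_A_null = c(logit(par$p0), logit(par$p1 / (1 - par$p0)),
                           logit(par$omega0))
  )
}

# transformed optimizer vector -> natural parameter list
model_par_unpack <- function(name, theta) {
  switch(name,
    M0 = list(omega = exp(theta[1])),
    M1a = list(p0 = inv_logit(theta[1]), omega0 = inv_logit(theta[2])),
    M2a = {
      p0 <- inv_logit(theta[1]); p1 <- (1 - p0) * inv_logit(theta[2])
      list(p0 = p0, p1 = p1, omega0 = inv_logit(theta[3]),
           omega2 = 1 + exp(theta[4]))
    },
    M7 = list(p = exp(theta[1]), q = exp(theta[2])),
    M8 = list(p0 = inv_logit(theta[1]), p = exp(theta[2]), q = exp(theta[3]),
              omega_s = 1 + exp(theta[4])),
    branch_site_A = {
      p0 <- inv_logit(theta[1]); p1 <- (1 - p0) * inv_logit(theta[2])
      list(p0 = p0, p1 = p1, omega0 = inv_logit(theta[3]),
           omega2 = 1 + exp(theta[4]))
    },
    branch_site_A_null = {
      p0 <- inv_logit(theta[1]); p1 <- (1 - p0) * inv_logit(theta[2])
      list(p0 = p0, p1 = p1, omega0 = inv_logit(theta[3]))
    }
  )
}

# realize a site_class_model from natural parameters
model_realize <- function(name, par, K = 10) {
  switch(name,
    M0 = site_class_model("M0", omega = par$omega),
    M1a = site_class_model("M1a", p0 = par$p0, omega0 = par$omega0),
    M2a = site_class_model("M2a", p0 = par$p0, p1 = par$p1,
                           omega0 = par$omega0, omega2 = par$omega2),
    M7 = site_class_model("M7", p = par$p, q = par$q, K = K),
    M8 = site_class_model("M8", p0 = par$p0, p = par$p, q = par$q,
                          omega_s = par$omega_s, K = K),
    branch_site_A = site_class_model("branch_site_A", p0 = par$p0,
                                     p1 = par$p1, omega0 = par$omega0,
                                     omega2 = par$omega2),
    branch_site_A_null = site_class_model("branch_site_A_null", p0 = par$p0,
                                          p1 = par$p1, omega0 = par$omega0)
  )
}

# model-specific starting values given a starting omega
model_start_par <- function(name, start_omega) {
  w01 <- min(max(start_omega, 0.02), 0.9)   # squeezed into (0,1)
  wpos <- max(start_omega, 1.5)             # pushed above 1
  switch(name,
    M0 = list(omega = max(start_omega, 1e-3)),
    M1a = list(p0 = 0.7, omega0 = w01),
    M2a = list(p0 = 0.6, p1 = 0.3, omega0 = w01, omega2 = wpos),
    M7 = list(p = max(0.2, 2 * w01), q = max(0.2, 2 * (1 - w01))),
    M8 = list(p0 = 0.9, p = max(0.2, 2 * w01), q = max(0.2, 2 * (1 - w01)),
              omega_s = wpos),
    branch_site_A = list(p0 = 0.6, p1 = 0.3, omega0 = w01, omega2 = wpos),
    branch_site_A_null = list(p0 = 0.6, p1 = 0.3, omega0 = w01)
  )
}
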
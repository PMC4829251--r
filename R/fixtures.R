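#' Reference fixtures for testing and examples
#'
#' `"constant_rate"` returns a parameter set in the telegraph-process limit:
#' no age dependence (`A1` = 0, `lam` = 0) and no episode-induced remodelling
#' (`alpha = beta = mu = nu = 0`), leaving constant switching rates
#' `A0 = activation` and `R0 = recovery`. In this limit the long-run fraction
#' of time in AF is `activation / (activation + recovery)` and the mean
#' episode duration is `1 / recovery` — closed forms used throughout the test
#' suite. The set deliberately breaks the strict-positivity constraints of
#' the full model; simulate it with `check = FALSE`.
#'
#' `"toy_episodes"` returns a small hand-written trajectory (a 10-minute
#' episode at age 45, an 8-day episode at age 60, and a censored episode from
#' age 70 to the horizon) exercising all three stage-classification rules.
#'
#' @param kind `"constant_rate"` or `"toy_episodes"`.
#' @param seed Seed recorded on the fixture (fixtures are deterministic).
#' @param activation,recovery Constant switching rates (1/yr) for
#'   `"constant_rate"`.
#' @return An `af_params` object, or an `af_trajectory`.
#' @export
#' @examples
#' make_fixture("constant_rate")$A1 # 0
make_fixture <- function(kind = c("constant_rate", "toy_episodes"), seed = 1L,
                         activation = 20, recovery = 50) {
  kind <- match.arg(kind)
  if (kind == "constant_rate") {
    af_params(A0 = activation, A1 = 0, Amax = 0, alpha = 0, beta = 0,
              R0 = recovery, lam = 0, mu = 0, nu = 0, B = 0)
  } else {
    tc <- time_conventions()
    new_af_trajectory(
      start = c(45, 60, 70),
      end = c(45 + 10 / (24 * 60) / tc$days_per_year,
              60 + 8 / tc$days_per_year,
              100),
      censored = c(FALSE, FALSE, TRUE),
      params = af_params(), seed = seed, horizon = 100
    )
  }
}
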
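#' Time and threshold conventions
#'
#' Internal time unit is years throughout the package; all rates are stored in
#' 1/yr. Conversions use a 365-day year (so 31,536,000 seconds per year), which
#' is consistent with the age-related activation plateau of 365 x 8 episodes
#' per year and with the paroxysmal threshold of 1% of a day (14.4 minutes).
#'
#' @return A named list with elements `seconds_per_year`, `days_per_year`,
#'   `paroxysmal_threshold` (14.4 min in years), `persistent_threshold`
#'   (7 days in years) and `horizon` (default simulation end, 100 yr).
#' @export
#' @examples
#' time_conventions()$paroxysmal_threshold * 365 * 24 * 60 # 14.4 minutes
time_conventions <- function() {
  list(
    seconds_per_year = 31536000,
    days_per_year = 365,
    paroxysmal_threshold = 0.01 / 365,
    persistent_threshold = 7 / 365,
    horizon = 100
  )
}

#' Model parameters for the AF progression model
#'
#' Builds the 12-parameter set controlling the two-state switching model.
#' Defaults are the baseline set: activation of an AF episode while in sinus
#' rhythm has a constant genetic component `A0`, a sigmoidal age/co-morbidity
#' component rising to `A1` around age `tc` over width `td`, and an
#' episode-induced component that grows towards `Amax` at rate `alpha` during
#' AF and relaxes at rate `beta` in sinus rhythm. Recovery from AF has an
#' age-related component decaying from `R0` at rate `lam`; during AF the total
#' recovery rate decays at rate `mu`, and the episode-induced component relaxes
#' at rate `nu` in sinus rhythm, after a post-episode boost by factor `B`.
#'
#' All rates are in 1/yr. `R0` is conventionally quoted in 1/s (the baseline
#' value of 2/s corresponds to a shortest possible episode of 0.5 s); supply it
#' here already converted, or use `R0_per_second`.
#'
#' `mu` and `nu` default to `alpha` and `beta` respectively, mirroring the
#' assumption that episode-induced degradation and relaxation of the recovery
#' rate track those of the activation rate.
#'
#' @param A0 Genetic-predisposition activation rate, 1/yr.
#' @param A1 Maximum age/disease activation rate, 1/yr.
#' @param Amax Maximum episode-induced activation rate, 1/yr.
#' @param tc Age/disease sigmoid centre, yr.
#' @param td Age/disease sigmoid width, yr.
#' @param alpha Episode activation saturation rate, 1/yr.
#' @param beta Episode activation relaxation rate, 1/yr.
#' @param R0 Peak recovery rate of a newborn, 1/yr.
#' @param R0_per_second Alternative way to give `R0`, in 1/s; overrides `R0`.
#' @param lam Natural degradation rate of the age-related recovery rate, 1/yr.
#'   The baseline value is `1.2 * log(840) / 50` (natural log); see
#'   [lambda_derived()] for the analytically derived alternative.
#' @param mu Degradation rate of the total recovery rate during AF, 1/yr.
#' @param nu Relaxation rate of the episode recovery component in sinus
#'   rhythm, 1/yr.
#' @param B Post-episode recovery boost factor, dimensionless (1 = full
#'   reflection of the episode-induced deficit, 0 = no overshoot).
#' @return An object of class `af_params`: a named list of the 12 rates.
#' @seealso [validate_params()], [param_variant()], [lambda_derived()]
#' @export
#' @examples
#' p <- af_params()
#' p$Amax / p$A1 # episode-induced ceiling is twice the age-related plateau
af_params <- function(A0 = 1e-5,
                      A1 = 2920,
                      Amax = 2 * A1,
                      tc = 70,
                      td = 3,
                      alpha = 52,
                      beta = 182.5,
                      R0 = NULL,
                      R0_per_second = NULL,
                      lam = 1.2 * log(840) / 50,
                      mu = alpha,
                      nu = beta,
                      B = 1) {
  spy <- time_conventions()$seconds_per_year
  if (!is.null(R0_per_second)) {
    R0 <- R0_per_second * spy
  } else if (is.null(R0)) {
    R0 <- 2 * spy
  }
  p <- list(A0 = A0, A1 = A1, Amax = Amax, tc = tc, td = td,
            alpha = alpha, beta = beta, R0 = R0, lam = lam,
            mu = mu, nu = nu, B = B)
  ok <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
               logical(1))
  if (!all(ok)) {
    stop("all parameters must be finite numeric scalars; offending: ",
         paste(names(p)[!ok], collapse = ", "))
  }
  structure(lapply(p, as.double), class = "af_params")
}

#' @export
print.af_params <- function(x, ...) {
  cat("<af_params> (rates in 1/yr)\n")
  df <- data.frame(value = unlist(x))
  print(format(df, digits = 6))
  viol <- validate_params(x)
  if (nrow(viol) > 0) {
    cat("invalid:", nrow(viol), "constraint violation(s); see validate_params()\n")
  }
  invisible(x)
}

#' Analytically derived recovery decay rate
#'
#' The decay rate of the age-related recovery rate can be derived by requiring
#' that, starting from a peak recovery rate of 2/s at birth, a typical episode
#' at age 50 lasts 14.4 minutes (1% of a day, i.e. 864 s): this gives
#' `log(864 * 2) / 50` per year. The baseline set instead uses the slightly
#' larger `1.2 * log(840) / 50`; this helper exposes the derived value so it
#' can be swapped in via `af_params(lam = lambda_derived())`.
#'
#' @return The derived decay rate, 1/yr.
#' @export
lambda_derived <- function() log(864 * 2) / 50

#' Validate a parameter set
#'
#' Checks the structural constraints of the model: all rates strictly
#' positive, `B >= 0`, `td > 0`, `tc >= 0`, `Amax >= A1`, and `mu > lam` (the
#' total recovery rate must degrade faster during AF than the age-related
#' baseline declines in sinus rhythm, otherwise episodes could make recovery
#' *more* likely than the age baseline for the wrong reason).
#'
#' @param params An [af_params()] object.
#' @return A tibble with columns `field` and `rule`, one row per violated
#'   constraint; zero rows when the set is valid. Violations are reported, not
#'   raised.
#' @export
#' @examples
#' validate_params(af_params()) # zero rows
#' validate_params(af_params(td = 0)) # names td
validate_params <- function(params) {
  stopifnot(inherits(params, "af_params"))
  v <- list()
  add <- function(field, rule) v[[length(v) + 1]] <<- tibble::tibble(field = field, rule = rule)
  for (f in c("A0", "A1", "Amax", "alpha", "beta", "R0", "lam", "mu", "nu")) {
    if (params[[f]] <= 0) add(f, paste0(f, " must be strictly positive"))
  }
  if (params$B < 0) add("B", "B must be >= 0")
  if (params$td <= 0) add("td", "td must be > 0")
  if (params$tc < 0) add("tc", "tc must be >= 0")
  if (params$Amax < params$A1) add("Amax", "Amax must be >= A1")
  if (params$mu <= params$lam) add("mu", "mu must be > lam")
  if (length(v) == 0) {
    tibble::tibble(field = character(), rule = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Derive a single-parameter variant
#'
#' Returns a copy of `params` with one field rescaled or shifted, as used in
#' one-at-a-time sensitivity scans (e.g. `A1` scaled by 0.1 gives `A1 = 292`;
#' `tc` shifted by -10 gives an earlier age-related transition).
#'
#' @param params An [af_params()] object.
#' @param field Name of the parameter to change.
#' @param mode `"scale"` (multiply) or `"shift"` (add).
#' @param value The factor or offset.
#' @param quiet Suppress the warning issued when the variant violates the
#'   model constraints (deliberate experiments).
#' @return A new `af_params` object.
#' @export
#' @examples
#' param_variant(af_params(), "A1", "scale", 0.1)$A1 # 292
param_variant <- function(params, field, mode = c("scale", "shift"), value,
                          quiet = FALSE) {
  stopifnot(inherits(params, "af_params"))
  mode <- match.arg(mode)
  if (!field %in% names(params)) {
    stop("unknown parameter field: ", field)
  }
  out <- params
  out[[field]] <- switch(mode,
    scale = params[[field]] * value,
    shift = params[[field]] + value
  )
  viol <- validate_params(out)
  if (nrow(viol) > 0 && !quiet) {
    warning("variant violates model constraints: ",
            paste(viol$rule, collapse = "; "))
  }
  out
}

config_keys <- function() {
  c("A0", "A1", "Amax", "tc", "td", "alpha", "beta", "R0", "R0_unit",
    "lam", "mu", "nu", "B", "horizon",
    "paroxysmal_threshold_days", "persistent_threshold_days")
}

#' Read a model configuration file
#'
#' Reads a flat YAML or JSON map of the 12 model parameters plus optional
#' `R0_unit` ("per_second" or "per_year", default "per_second"), `horizon`
#' (yr), and stage thresholds in days. Unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `params` ([af_params()]), `horizon`, and
#'   `thresholds` (list with `paroxysmal`, `persistent`, in years).
#' @export
read_af_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(cfg), config_keys())
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  required <- c("A0", "A1", "Amax", "tc", "td", "alpha", "beta", "R0",
                "lam", "mu", "nu", "B")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    stop("missing config key(s): ", paste(missing, collapse = ", "))
  }
  # numeric fields may arrive as strings (e.g. YAML "1e-5"); coerce
  for (k in setdiff(names(cfg), "R0_unit")) {
    if (is.character(cfg[[k]])) {
      v <- suppressWarnings(as.numeric(cfg[[k]]))
      if (is.na(v)) stop("config key ", k, " is not numeric: ", cfg[[k]])
      cfg[[k]] <- v
    }
  }
  unit <- cfg$R0_unit %||% "per_second"
  if (!unit %in% c("per_second", "per_year")) {
    stop("R0_unit must be 'per_second' or 'per_year', got: ", unit)
  }
  tc_conv <- time_conventions()
  R0 <- if (unit == "per_second") cfg$R0 * tc_conv$seconds_per_year else cfg$R0
  params <- af_params(
    A0 = cfg$A0, A1 = cfg$A1, Amax = cfg$Amax, tc = cfg$tc, td = cfg$td,
    alpha = cfg$alpha, beta = cfg$beta, R0 = R0, lam = cfg$lam,
    mu = cfg$mu, nu = cfg$nu, B = cfg$B
  )
  list(
    params = params,
    horizon = cfg$horizon %||% tc_conv$horizon,
    thresholds = list(
      paroxysmal = (cfg$paroxysmal_threshold_days %||% 0.01) / tc_conv$days_per_year,
      persistent = (cfg$persistent_threshold_days %||% 7) / tc_conv$days_per_year
    )
  )
}

#' Write a model configuration file
#'
#' Serialises a parameter set (plus horizon) to a flat YAML or JSON map that
#' [read_af_config()] parses back to the identical parameters to machine
#' precision. `R0` is written in 1/yr with an explicit unit tag.
#'
#' @param params An [af_params()] object.
#' @param path Output path; format chosen by extension (`.json` vs `.yaml`).
#' @param horizon Simulation horizon in years.
#' @return `path`, invisibly.
#' @export
write_af_config <- function(params, path, horizon = time_conventions()$horizon) {
  stopifnot(inherits(params, "af_params"))
  cfg <- c(unclass(params), list(R0_unit = "per_year", horizon = horizon))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = I(17))
  } else {
    # flat map written by hand so numbers keep full precision through YAML
    num <- vapply(cfg, function(x) {
      if (is.character(x)) x else sprintf("%.17g", x)
    }, character(1))
    writeLines(paste0(names(cfg), ": ", num), path)
  }
  invisible(path)
}
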
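#' Model parameters for the refuge-modified Leslie-Gower system
#'
#' Constructs and validates the eight coefficients of the predator-prey
#' system
#' \deqn{\dot x = \left(r_1 - b_1 x - \frac{a_1(1-m)y}{(1-m)x + k_1}\right)x,
#'   \qquad
#'   \dot y = \left(r_2 - \frac{a_2 y}{(1-m)x + k_2}\right)y.}
#' A fixed fraction \eqn{m} of the prey population is protected by a refuge,
#' so only \eqn{(1-m)x} prey are available to the predator; the predator's
#' carrying capacity \eqn{r_2((1-m)x + k_2)/a_2} is proportional to the
#' available prey plus its environmental protection constant (the
#' Leslie-Gower term).
#'
#' @param r1 prey intrinsic growth rate (1/time, > 0).
#' @param b1 prey intraspecific competition coefficient
#'   (1/(time x density), > 0); `r1/b1` is the prey carrying capacity.
#' @param a1 maximum per-capita prey reduction rate by predation (> 0).
#' @param k1 environmental protection constant for the prey
#'   (half-saturation density of the Holling type II response, > 0).
#' @param r2 predator intrinsic growth rate (> 0).
#' @param a2 measure of food quantity the prey provides, converted to
#'   predator births (> 0).
#' @param k2 environmental protection constant for the predator
#'   (alternate food; density, >= 0). `k2 = 0` means the predator has no
#'   alternate food (the Holling-Tanner case) and must be opted into
#'   explicitly via `holling_tanner = TRUE`, because the predator equation
#'   is then singular at `x = 0`.
#' @param m refuge fraction, dimensionless, in `[0, 1)`. `m = 0` recovers
#'   the refuge-free modified Leslie-Gower model.
#' @param holling_tanner logical; set `TRUE` to permit `k2 = 0`.
#'
#' @return An object of class `lg_params`: a named list with the eight
#'   coefficients and the `holling_tanner` flag.
#' @examples
#' p <- lg_params(r1 = 11, b1 = 5, a1 = 4, k1 = 6.5,
#'                r2 = 8, a2 = 2, k2 = 2, m = 0.4)
#' p
#' @seealso [lg_params_from_file()] to read the same fields from a
#'   JSON or YAML configuration file.
#' @export
lg_params <- function(r1, b1, a1, k1, r2, a2, k2, m = 0,
                      holling_tanner = FALSE) {
  p <- list(r1 = r1, b1 = b1, a1 = a1, k1 = k1,
            r2 = r2, a2 = a2, k2 = k2, m = m,
            holling_tanner = isTRUE(holling_tanner))
  validate_params(p)
  class(p) <- "lg_params"
  p
}

# Domain checks; error messages name the violated invariant.
validate_params <- function(p) {
  num <- c("r1", "b1", "a1", "k1", "r2", "a2", "k2", "m")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  pos <- c("r1", "b1", "a1", "k1", "r2", "a2")
  for (nm in pos) {
    if (p[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive (got ",
           p[[nm]], ")", call. = FALSE)
  }
  if (p$m < 0 || p$m >= 1)
    stop("refuge fraction 'm' must lie in [0, 1) (got ", p$m, ")",
         call. = FALSE)
  if (p$k2 < 0)
    stop("parameter 'k2' must be non-negative (got ", p$k2, ")",
         call. = FALSE)
  if (p$k2 == 0 && !isTRUE(p$holling_tanner))
    stop("k2 = 0 makes the predator equation singular at x = 0 ",
         "(Holling-Tanner mode); pass holling_tanner = TRUE to opt in",
         call. = FALSE)
  invisible(p)
}

#' @export
print.lg_params <- function(x, ...) {
  cat("Leslie-Gower predator-prey parameters (prey refuge m = ",
      format(x$m), ")\n", sep = "")
  cat(sprintf("  prey:     r1 = %-8g b1 = %-8g a1 = %-8g k1 = %g\n",
              x$r1, x$b1, x$a1, x$k1))
  cat(sprintf("  predator: r2 = %-8g a2 = %-8g k2 = %g%s\n",
              x$r2, x$a2, x$k2,
              if (x$k2 == 0) "  [Holling-Tanner]" else ""))
  invisible(x)
}

#' Read model parameters from a configuration file
#'
#' Reads the eight coefficient fields (`r1`, `b1`, `a1`, `k1`, `r2`, `a2`,
#' `k2`, `m`) plus an optional `holling_tanner` flag from a flat JSON or
#' YAML file and validates them via [lg_params()]. The same schema is used
#' by every command-line subcommand.
#'
#' @param path path to a `.json`, `.yml` or `.yaml` file.
#' @return An `lg_params` object.
#' @export
lg_params_from_file <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yml  = ,
    yaml = yaml::read_yaml(path),
    stop("unsupported config format '.", ext,
         "' (expected .json, .yml or .yaml)", call. = FALSE))
  need <- c("r1", "b1", "a1", "k1", "r2", "a2", "k2", "m")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("config is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  lg_params(r1 = cfg$r1, b1 = cfg$b1, a1 = cfg$a1, k1 = cfg$k1,
            r2 = cfg$r2, a2 = cfg$a2, k2 = cfg$k2, m = cfg$m,
            holling_tanner = isTRUE(cfg$holling_tanner))
}

as_params <- function(p) {
  if (!inherits(p, "lg_params"))
    stop("expected an 'lg_params' object; see lg_params()", call. = FALSE)
  p
}
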
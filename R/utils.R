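`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
is_uncertain_value <- function(x) inherits(x, "uncertain_value")

# Evaluate with the global RNG stream saved and restored, so seeded
# generators do not clobber the caller's random state.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read a scalar model parameter by path
#'
#' Paths address scalars inside a parameter set: `"cost_tgt"` resolves to the
#' mean of that uncertain value, `"cost_tgt.sd_override"` to a component,
#' `"prevalence_exon9"` to the plain numeric field.
#'
#' @param params a `gist_params` object.
#' @param path character scalar, e.g. `"cost_sunitinib_year"`.
#' @return numeric scalar.
#' @export
get_param <- function(params, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  field <- parts[1]
  if (!field %in% names(params))
    stop("unknown parameter path: '", path, "'", call. = FALSE)
  x <- params[[field]]
  if (is_uncertain_value(x)) {
    comp <- if (length(parts) > 1) parts[2] else "mean"
    if (!comp %in% names(x))
      stop("unknown component '", comp, "' in path '", path, "'", call. = FALSE)
    return(x[[comp]] %||% NA_real_)
  }
  if (length(parts) > 1)
    stop("parameter '", field, "' has no components", call. = FALSE)
  x
}

#' Set a scalar model parameter by path
#'
#' Mirrors [get_param()]. Two paths carry model-specific side effects,
#' mirroring how the underlying quantities are linked:
#' \itemize{
#'   \item `prevalence_exon9`: the exon 11 and "other" prevalences are
#'     rescaled proportionally so the three still sum to one.
#'   \item `cost_imatinib400_year`: the 800 mg cost is kept at exactly twice
#'     the 400 mg cost, and the brand/generic prices are rescaled by the same
#'     factor so the market-share identity is preserved.
#' }
#'
#' @param params a `gist_params` object.
#' @param path character scalar parameter path.
#' @param value numeric scalar replacement.
#' @return the modified `gist_params` object.
#' @export
set_param <- function(params, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  field <- parts[1]
  if (!field %in% names(params))
    stop("unknown parameter path: '", path, "'", call. = FALSE)

  if (field == "prevalence_exon9" && length(parts) == 1) {
    rest <- params$prevalence_exon11 + params$prevalence_other
    if (rest <= 0) stop("cannot renormalize: other prevalences are zero", call. = FALSE)
    scale <- (1 - value) / rest
    params$prevalence_exon9 <- value
    params$prevalence_exon11 <- params$prevalence_exon11 * scale
    params$prevalence_other <- params$prevalence_other * scale
    return(params)
  }
  if (field == "cost_imatinib400_year" && (length(parts) == 1 || parts[2] == "mean")) {
    old <- params$cost_imatinib400_year$mean
    params$cost_imatinib400_year$mean <- value
    params$cost_imatinib800_year$mean <- 2 * value
    if (old > 0) {
      f <- value / old
      params$price_brand_imatinib400_year <- params$price_brand_imatinib400_year * f
      params$price_generic_imatinib400_year <- params$price_generic_imatinib400_year * f
    }
    return(params)
  }

  x <- params[[field]]
  if (is_uncertain_value(x)) {
    comp <- if (length(parts) > 1) parts[2] else "mean"
    if (!comp %in% names(x))
      stop("unknown component '", comp, "' in path '", path, "'", call. = FALSE)
    x[[comp]] <- value
    params[[field]] <- x
  } else {
    if (length(parts) > 1)
      stop("parameter '", field, "' has no components", call. = FALSE)
    params[[field]] <- value
  }
  params
}
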
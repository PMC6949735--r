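# ADME screening: continuous Tanimoto drug-likeness, the eight-descriptor
# half-life regression, and the OB/DL/HL threshold screen with a per-row
# audit of which criteria each ingredient failed.

#' Continuous Tanimoto drug-likeness score
#'
#' Scores a compound's molecular-descriptor vector `x` against the average
#' descriptor vector `y` of a reference drug library (e.g. the DrugBank
#' centroid):
#'
#' \deqn{T(x, y) = \frac{x \cdot y}{\|x\|^2 + \|y\|^2 - x \cdot y}}
#'
#' The score is symmetric and equals 1 exactly when `x == y != 0`. Unlike the
#' binary Tanimoto coefficient this continuous form is *not* scale-invariant:
#' `tanimoto_dl(2 * x, y)` generally differs from `tanimoto_dl(x, y)`. That
#' is a property of the published form and is preserved, not "fixed".
#'
#' @param x Numeric descriptor vector of a compound.
#' @param y Numeric reference-centroid vector of the same length.
#' @return The Tanimoto score, a single number.
#' @examples
#' tanimoto_dl(c(1, 2, 3), c(1, 2, 3)) # 1
#' tanimoto_dl(c(1, 0), c(0, 1))       # 0
#' @export
tanimoto_dl <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("descriptor vectors have different dimensions (", length(x),
         " vs ", length(y), ")", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("descriptor vectors must be finite", call. = FALSE)
  }
  xy <- sum(x * y)
  denom <- sum(x * x) + sum(y * y) - xy
  if (denom == 0) {
    stop("Tanimoto score undefined: both vectors are zero (denominator 0)",
         call. = FALSE)
  }
  xy / denom
}

# the eight QSPR descriptors of the half-life model, in canonical order
.hl_descriptors <- c("nArCO", "H7m", "DDr09", "N070", "C032", "JGI6",
                     "nRCeqN", "Mor02e")

#' Construct a half-life regression model
#'
#' A linear QSPR model predicting half-life (hours) from eight molecular
#' descriptors: nArCO (aromatic ketone count), H7m (GETAWAY H autocorrelation),
#' D/Dr09 (distance/detour ring index, stored as `DDr09`), N-070 (`N070`,
#' atom-centred N fragment), C-032 (`C032`, atom-centred C fragment), JGI6
#' (topological charge index), nRC=N (`nRCeqN`, imine count) and Mor02e
#' (3D-MoRSE descriptor). The packaged default carries the published point
#' estimates; standard errors are not recoverable and are not stored.
#'
#' @param intercept Intercept in hours.
#' @param coef Named numeric vector or list covering exactly the eight
#'   descriptor names `nArCO, H7m, DDr09, N070, C032, JGI6, nRCeqN, Mor02e`.
#' @param metadata Optional list of fit statistics kept for provenance
#'   (`r2`, `q2`, `f_stat`, `see`, `n_training`, `n_test`).
#' @return An object of class `hl_model`.
#' @seealso [hl_model_default()], [predict_hl()]
#' @export
hl_model <- function(intercept, coef, metadata = list()) {
  coef <- unlist(coef)
  if (!setequal(names(coef), .hl_descriptors) ||
      length(coef) != length(.hl_descriptors)) {
    stop("coef must cover exactly the descriptors: ",
         paste(.hl_descriptors, collapse = ", "), call. = FALSE)
  }
  coef <- coef[.hl_descriptors]
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            all(is.finite(coef)))
  structure(list(intercept = as.numeric(intercept), coef = coef,
                 metadata = metadata),
            class = "hl_model")
}

#' @export
print.hl_model <- function(x, ...) {
  cat("Half-life regression model (hours)\n")
  cat("  intercept:", format(x$intercept), "\n")
  for (k in names(x$coef)) cat(sprintf("  %-7s %+.3f\n", k, x$coef[[k]]))
  if (length(x$metadata)) {
    cat("  fit:", paste(names(x$metadata), unlist(x$metadata),
                        sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Packaged default half-life model
#'
#' Loads the point-estimate coefficients shipped in `hl_model_eq2.json`
#' (intercept 13.310 h; slopes for the eight descriptors; fit metadata
#' R2 = 0.65, Q2 = 0.62, F = 27.272, SEE = 8.127, 126 training / 43 test
#' compounds). A different coefficient file can be supplied to override the
#' model wholesale.
#'
#' @param path Path to a JSON file with fields `intercept`, `coef` (eight
#'   named numbers) and optional `metadata`.
#' @return An [hl_model()] object.
#' @export
hl_model_default <- function(path = herbnet_extdata("hl_model_eq2.json")) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  hl_model(spec$intercept, spec$coef, as.list(spec$metadata))
}

#' Predict half-life from QSPR descriptors
#'
#' Evaluates the linear predictor `intercept + sum(coef[k] * d[k])` over the
#' eight descriptors of an [hl_model()].
#'
#' @param d Named numeric vector or list of descriptor values; must contain
#'   all eight descriptor names of the model (extra names are an error).
#' @param model An [hl_model()]; defaults to the packaged coefficients.
#' @return Predicted half-life in hours.
#' @examples
#' d0 <- setNames(numeric(8), names(hl_model_default()$coef))
#' predict_hl(d0) # intercept only: 13.31
#' @export
predict_hl <- function(d, model = hl_model_default()) {
  stopifnot(inherits(model, "hl_model"))
  d <- unlist(d)
  missing_d <- setdiff(names(model$coef), names(d))
  if (length(missing_d)) {
    stop("missing descriptor(s): ", paste(missing_d, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(d), names(model$coef))
  if (length(extra)) {
    stop("unknown descriptor(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  d <- d[names(model$coef)]
  if (!all(is.finite(d))) stop("descriptor values must be finite", call. = FALSE)
  unname(model$intercept + sum(model$coef * d))
}

#' Screening criteria for the ADME filter
#'
#' The three-criterion bioactivity screen: oral bioavailability at least
#' `ob_min` percent, drug-likeness at least `dl_min`, and half-life inside
#' `[hl_min, hl_max]` hours. All bounds are inclusive, and comparisons run on
#' the stored values without re-rounding.
#'
#' @param ob_min Minimum oral bioavailability, percent (default 30).
#' @param dl_min Minimum drug-likeness index (default 0.18).
#' @param hl_min,hl_max Half-life window in hours (defaults 4 and 8).
#' @return An object of class `screening_criteria`.
#' @export
screening_criteria <- function(ob_min = 30, dl_min = 0.18,
                               hl_min = 4, hl_max = 8) {
  stopifnot(is.numeric(ob_min), ob_min >= 0,
            is.numeric(dl_min), dl_min >= 0, dl_min <= 1,
            is.numeric(hl_min), is.numeric(hl_max), hl_min <= hl_max)
  structure(list(ob_min = ob_min, dl_min = dl_min,
                 hl_min = hl_min, hl_max = hl_max),
            class = "screening_criteria")
}

#' Packaged default screening criteria
#'
#' Reads `criteria_default.json` (OB >= 30%, DL >= 0.18, 4 <= HL <= 8 h).
#'
#' @param path Path to a JSON criteria file.
#' @return A [screening_criteria()] object.
#' @export
criteria_default <- function(path = herbnet_extdata("criteria_default.json")) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  screening_criteria(x$ob_min, x$dl_min, x$hl_min, x$hl_max)
}

#' Screen an ingredient catalogue on OB/DL/HL
#'
#' Tests every ingredient against all three criteria and records every
#' violated criterion, not just the first. A missing (`NA`) value fails its
#' criterion with reason `"missing"`. The result partitions the input: each
#' row is either in the pass set or carries a non-empty list of failed
#' criteria.
#'
#' @param ingredients Data frame from [read_ingredient_catalogue()] (needs
#'   columns `ingredient_id`, `ob`, `dl`, `hl`).
#' @param criteria A [screening_criteria()] object.
#' @return An object of class `screen_report`: a list with
#'   \describe{
#'     \item{report}{per-ingredient audit — the compared values, a `pass`
#'       flag, and `failed` (comma-joined subset of `OB,DL,HL`, with
#'       `:missing` suffixes for absent values).}
#'     \item{pass}{the passing rows of `ingredients`, input order preserved.}
#'     \item{fail}{the complement.}
#'     \item{n_total,n_pass,n_fail}{summary counts.}
#'     \item{criteria}{the criteria applied.}
#'   }
#' @examples
#' rep <- screen(table1_fixture())
#' rep$n_pass
#' @export
screen <- function(ingredients, criteria = screening_criteria()) {
  stopifnot(is.data.frame(ingredients),
            inherits(criteria, "screening_criteria"))
  need <- c("ingredient_id", "ob", "dl", "hl")
  miss <- setdiff(need, names(ingredients))
  if (length(miss)) {
    stop("ingredients lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(ingredients)
  fail_of <- function(value, ok, label) {
    ifelse(is.na(value), paste0(label, ":missing"), ifelse(ok, NA, label))
  }
  f_ob <- fail_of(ingredients$ob, ingredients$ob >= criteria$ob_min, "OB")
  f_dl <- fail_of(ingredients$dl, ingredients$dl >= criteria$dl_min, "DL")
  f_hl <- fail_of(ingredients$hl,
                  ingredients$hl >= criteria$hl_min &
                    ingredients$hl <= criteria$hl_max, "HL")
  failed <- vapply(seq_len(n), function(i) {
    paste(stats::na.omit(c(f_ob[i], f_dl[i], f_hl[i])), collapse = ",")
  }, character(1))
  pass <- !nzchar(failed)
  report <- data.frame(
    ingredient_id = ingredients$ingredient_id,
    name = if ("name" %in% names(ingredients)) ingredients$name else NA_character_,
    ob = ingredients$ob, dl = ingredients$dl, hl = ingredients$hl,
    pass = pass, failed = failed,
    stringsAsFactors = FALSE
  )
  structure(list(report = report,
                 pass = ingredients[pass, , drop = FALSE],
                 fail = ingredients[!pass, , drop = FALSE],
                 n_total = n, n_pass = sum(pass), n_fail = sum(!pass),
                 criteria = criteria),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cr <- x$criteria
  cat(sprintf(
    "ADME screen (OB >= %g%%, DL >= %g, %g <= HL <= %g h): %d of %d pass (%s%%)\n",
    cr$ob_min, cr$dl_min, cr$hl_min, cr$hl_max, x$n_pass, x$n_total,
    format(retention_rate(x$n_pass, max(x$n_total, 1)), nsmall = 2)))
  if (x$n_fail) {
    cat("failed criteria by ingredient:\n")
    bad <- x$report[!x$report$pass, c("ingredient_id", "name", "failed")]
    print(utils::head(bad, 15), row.names = FALSE)
    if (nrow(bad) > 15) cat("  ... and", nrow(bad) - 15, "more\n")
  }
  invisible(x)
}

#' Retention rate of a screen
#'
#' Percentage of ingredients passing the screen, rounded half-up to two
#' decimal places (so 41 of 382 gives 10.73).
#'
#' @param n_pass,n_total Pass and total counts, `0 <= n_pass <= n_total`,
#'   `n_total > 0`.
#' @return The percentage `100 * n_pass / n_total`, 2 dp.
#' @export
retention_rate <- function(n_pass, n_total) {
  stopifnot(length(n_pass) == 1, length(n_total) == 1)
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  if (n_pass < 0 || n_pass > n_total) {
    stop("n_pass must lie in [0, n_total]", call. = FALSE)
  }
  pct <- 100 * n_pass / n_total
  # half-up to 2 dp (round() is round-half-even)
  floor(pct * 100 + 0.5) / 100
}
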
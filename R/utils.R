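# internal helpers shared across modules

# metadata columns that are never feature values
META_COLUMNS <- c(
  "obs_id", "patient_id", "lesion_id", "timepoint",
  "scanner", "kvp", "kernel", "exposure_time_ms", "tube_current_ma",
  "contrast_agent", "slice_thickness_mm", "batch_id"
)

#' Identify feature columns of a feature table
#'
#' Feature columns are all numeric columns that are not acquisition metadata
#' (`obs_id`, `patient_id`, `lesion_id`, `timepoint`, scanner/kVp/kernel and
#' the other protocol fields, `batch_id`).
#'
#' @param table A feature table (data frame).
#' @param features Optional character vector naming the feature columns; when
#'   supplied it is validated against `table` and returned as-is.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(table, features = NULL) {
  stopifnot(is.data.frame(table))
  if (!is.null(features)) {
    missing <- setdiff(features, names(table))
    if (length(missing) > 0L) {
      abort(paste0("Features not present in table: ",
                   paste(missing, collapse = ", ")))
    }
    return(features)
  }
  num <- vapply(table, is.numeric, logical(1))
  setdiff(names(table)[num], META_COLUMNS)
}

# deterministic child seed for a named random stream, keeps within 32-bit range
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) %% 2147480000 * 31 + h) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(paste0("`", name, "` must be positive and finite"))
  }
  invisible(x)
}

check_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower) {
    abort(paste0("`", name, "` must be a finite number >= ", lower))
  }
  invisible(x)
}
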
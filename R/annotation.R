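#' Sample annotation table
#'
#' Per-sample clinical annotation: diagnosis (FTC = follicular thyroid
#' carcinoma, FTA = follicular thyroid adenoma), the oncocytic (Hurthle cell)
#' flag, the dataset tier and optional covariates.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param diagnosis factor or character, values `"FTC"` / `"FTA"`.
#' @param oncocytic logical vector (default all `FALSE`).
#' @param tier dataset tier: `"primary"`, `"secondary"` or `"validation"`.
#' @param ... further per-sample covariates (e.g. `age`, `sex`, `ras_status`),
#'   each of length `length(sample_id)`.
#' @return A `data.frame` of class `sample_annotation`.
#' @export
sample_annotation <- function(sample_id, diagnosis,
                              oncocytic = rep(FALSE, length(sample_id)),
                              tier = "validation", ...) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicated sample ids: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  diagnosis <- as.character(diagnosis)
  if (length(diagnosis) != length(sample_id) || anyNA(diagnosis))
    stop("'diagnosis' must be given for every sample")
  if (!all(diagnosis %in% c("FTC", "FTA")))
    stop("'diagnosis' must be FTC or FTA")
  if (!all(tier %in% c("primary", "secondary", "validation")))
    stop("'tier' must be primary, secondary or validation")
  out <- data.frame(sample_id = sample_id,
                    diagnosis = factor(diagnosis, levels = c("FTA", "FTC")),
                    oncocytic = as.logical(oncocytic),
                    tier = rep_len(tier, length(sample_id)),
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  class(out) <- c("sample_annotation", "data.frame")
  out
}
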
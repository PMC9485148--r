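#' The seven left mandibular permanent teeth
#'
#' Tooth identities used throughout the package, in FDI two-digit
#' notation: 31 central incisor, 32 lateral incisor, 33 canine,
#' 34 first bicuspid (premolar), 35 second bicuspid, 36 first molar,
#' 37 second molar. The ordering is fixed and matches the row order of
#' published score tables.
#'
#' @return `tooth_ids()` returns a character vector of the seven FDI
#'   codes (`"31"` ... `"37"`); `tooth_labels()` returns the
#'   corresponding anatomical names; `tooth_columns()` the staging-CSV
#'   column names (`"t31"` ... `"t37"`).
#' @examples
#' tooth_ids()
#' tooth_labels()
#' @export
tooth_ids <- function() {
  c("31", "32", "33", "34", "35", "36", "37")
}

#' @rdname tooth_ids
#' @export
tooth_labels <- function() {
  c("31" = "Central incisor", "32" = "Lateral incisor", "33" = "Canine",
    "34" = "First bicuspid", "35" = "Second bicuspid",
    "36" = "First molar", "37" = "Second molar")
}

#' @rdname tooth_ids
#' @export
tooth_columns <- function() {
  paste0("t", tooth_ids())
}

#' Demirjian mineralization stages
#'
#' The eight ordinal stages A < B < ... < H of crown and root
#' mineralization read from a panoramic radiograph. An unscorable or
#' absent tooth is recorded as `NA` ("missing") in staging tables.
#'
#' @return Character vector `c("A", ..., "H")`.
#' @examples
#' stage_levels()
#' stage_code("D") # ordinal code, A = 1
#' @export
stage_levels <- function() {
  LETTERS[1:8]
}

#' @rdname stage_levels
#' @param stage character vector of stage letters (or `NA` for missing).
#' @return `stage_code()` returns integer ordinal codes A = 1 ... H = 8,
#'   with missing mapped to 0.
#' @export
stage_code <- function(stage) {
  code <- match(stage, stage_levels())
  code[is.na(stage)] <- 0L
  if (anyNA(code)) {
    bad <- unique(stage[!is.na(stage) & is.na(match(stage, stage_levels()))])
    abort(paste0("invalid stage letter(s): ", paste(bad, collapse = ", ")))
  }
  as.integer(code)
}

sex_levels <- function() c("female", "male")
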
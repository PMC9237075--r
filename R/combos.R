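# Modality bookkeeping. The four sequences have a fixed global stacking
# order -- T2-FLAIR, T1, T1ce, T2 -- and one-character codes f, 1, c, 2 in
# that same order, so every nonempty subset has a unique canonical code
# (the full combination is "f1c2").

MODALITIES <- c("FLAIR", "T1", "T1ce", "T2")
MODALITY_CODES <- c(FLAIR = "f", T1 = "1", T1ce = "c", T2 = "2")

#' Modality combination
#'
#' Builds a combination of MRI sequences from either a canonical code
#' (characters among `f`, `1`, `c`, `2`) or a character vector of modality
#' names (`"FLAIR"`, `"T1"`, `"T1ce"`, `"T2"`). Members are always stored in
#' the fixed global order FLAIR, T1, T1ce, T2 regardless of input order.
#'
#' @param x a code string such as `"f1c2"` or `"2"`, or a character vector of
#'   modality names.
#' @return an object of class `modality_combo` with fields `members` and
#'   `code`.
#' @export
modality_combo <- function(x) {
  if (inherits(x, "modality_combo")) return(x)
  stopifnot(is.character(x), length(x) >= 1)
  if (length(x) == 1L && !x %in% MODALITIES) {
    chars <- strsplit(x, "")[[1]]
    bad <- setdiff(chars, unname(MODALITY_CODES))
    if (length(bad) || length(chars) == 0L || anyDuplicated(chars))
      stop("invalid combination code: '", x, "'", call. = FALSE)
    members <- MODALITIES[match(chars, MODALITY_CODES)]
  } else {
    bad <- setdiff(x, MODALITIES)
    if (length(bad))
      stop("unknown modality: ", paste(bad, collapse = ", "), call. = FALSE)
    members <- unique(x)
  }
  members <- MODALITIES[MODALITIES %in% members]
  structure(list(members = members,
                 code = paste(MODALITY_CODES[members], collapse = "")),
            class = "modality_combo")
}

#' @export
print.modality_combo <- function(x, ...) {
  cat(sprintf("<modality_combo> %s (%s)\n", x$code,
              paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Enumerate all nonempty modality combinations
#'
#' The four sequences admit 2^4 - 1 = 15 nonempty subsets; this returns their
#' canonical codes in lexicographic order.
#'
#' @return character vector of 15 combination codes.
#' @export
all_modality_combos <- function() {
  idx <- 1:15
  codes <- vapply(idx, function(i) {
    keep <- as.logical(bitwAnd(i, c(1L, 2L, 4L, 8L)))
    paste(MODALITY_CODES[MODALITIES[keep]], collapse = "")
  }, character(1))
  sort(codes)
}
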
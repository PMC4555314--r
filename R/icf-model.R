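# ICF code and qualifier data model.
#
# Codes are plain character strings validated against the structural rules of
# the classification: a component letter (b body functions, s body structures,
# d activities/participation, e environmental factors) followed by 1, 3, 4 or
# 5 digits. Two-digit forms do not exist. The digit count determines the
# hierarchy level, and the parent of any non-chapter code is a prefix of it,
# so the whole hierarchy is derivable from code text alone.

ICF_COMPONENTS <- c("b", "s", "d", "e")

# digit count -> level name
ICF_LEVELS <- c(`1` = "chapter", `3` = "second", `4` = "third", `5` = "fourth")

#' Severity qualifiers of the ICF scale
#'
#' The ICF rates every category with an ordered severity qualifier:
#' 0 (no problem), 1 (mild), 2 (moderate), 3 (severe), 4 (complete), plus two
#' sentinel values outside the order: 8 (not specified) and 9 (not
#' applicable). Sentinels are excluded from all arithmetic.
#'
#' @format Integer vector of the seven admissible qualifier values.
#' @export
ICF_QUALIFIERS <- c(0L, 1L, 2L, 3L, 4L, 8L, 9L)

QUALIFIER_LABELS <- c(
  `0` = "no", `1` = "mild", `2` = "moderate", `3` = "severe",
  `4` = "complete", `8` = "not specified", `9` = "not applicable"
)

#' Human-readable label of a qualifier value
#'
#' @param q integer vector of qualifier values in `{0,1,2,3,4,8,9}`.
#' @return character vector of labels ("no", "mild", ..., "not applicable").
#' @examples
#' qualifier_label(c(0, 4, 8))
#' @export
qualifier_label <- function(q) {
  validate_qualifier(q)
  unname(QUALIFIER_LABELS[as.character(q)])
}

#' Is a qualifier one of the five ordered severity levels?
#'
#' @param q integer vector of qualifier values.
#' @return logical; `TRUE` for 0-4, `FALSE` for the sentinels 8 and 9 and for
#'   `NA`.
#' @export
is_ordered_qualifier <- function(q) {
  !is.na(q) & q %in% 0:4
}

validate_qualifier <- function(q, allow_na = FALSE) {
  bad <- if (allow_na) !is.na(q) & !(q %in% ICF_QUALIFIERS) else
    is.na(q) | !(q %in% ICF_QUALIFIERS)
  if (any(bad)) {
    stop("invalid qualifier value(s): ",
         paste(unique(q[bad]), collapse = ", "),
         " (admissible: 0-4, 8, 9)", call. = FALSE)
  }
  invisible(as.integer(q))
}

#' Compare two ordered qualifiers
#'
#' Only the severity levels 0-4 are ordered. Comparing a sentinel (8 or 9) is
#' a contract violation and raises an error rather than returning a silent
#' order.
#'
#' @param a,b qualifier values in 0-4.
#' @return integer: -1 if `a < b`, 0 if equal, 1 if `a > b`.
#' @export
compare_qualifiers <- function(a, b) {
  validate_qualifier(a)
  validate_qualifier(b)
  if (any(!is_ordered_qualifier(a)) || any(!is_ordered_qualifier(b))) {
    stop("sentinel qualifiers (8, 9) are unordered and cannot be compared",
         call. = FALSE)
  }
  as.integer(sign(a - b))
}

#' Parse and validate ICF code text
#'
#' An ICF code is a component letter (`b`, `s`, `d`, `e`) followed by 1, 3, 4
#' or 5 digits; two-digit forms are invalid. The hierarchy level is a pure
#' function of the digit count: 1 digit is a chapter, 3 a second-level, 4 a
#' third-level and 5 a fourth-level category.
#'
#' @param text character vector of code text, e.g. `"d550"`.
#' @return a tibble with one row per code and columns `code`, `component`
#'   and `level`.
#' @examples
#' parse_icf_code(c("d550", "b1641"))
#' @export
parse_icf_code <- function(text) {
  if (length(text) == 0 || any(is.na(text)) || any(!nzchar(text))) {
    stop("ICF code text must be non-empty", call. = FALSE)
  }
  text <- trimws(text)
  ok <- grepl("^[bsde][0-9]{1}([0-9]{2,4})?$", text)
  if (any(ok)) {
    ndig <- nchar(text[ok]) - 1L
    ok[ok] <- ndig %in% c(1L, 3L, 4L, 5L)
  }
  if (any(!ok)) {
    stop("malformed ICF code(s): ", paste(unique(text[!ok]), collapse = ", "),
         " (expected one of b/s/d/e followed by 1, 3, 4 or 5 digits)",
         call. = FALSE)
  }
  tibble::tibble(
    code = text,
    component = substr(text, 1L, 1L),
    level = unname(ICF_LEVELS[as.character(nchar(text) - 1L)])
  )
}

is_valid_icf_code <- function(text) {
  !is.na(text) & grepl("^[bsde][0-9]{1}([0-9]{2,4})?$", text) &
    (nchar(text) - 1L) %in% c(1L, 3L, 4L, 5L)
}

#' Parent code in the ICF hierarchy
#'
#' The parent of a second-level code is its chapter (1 digit), of a
#' third-level code its second-level prefix (3 digits), and of a fourth-level
#' code its third-level prefix (4 digits). Chapters are roots and have no
#' parent. Parent-category values are computed as the average of the lower
#' categories that carry a value, so rollup stops at the chapter.
#'
#' @param code character vector of valid ICF codes.
#' @return character vector of parent codes, `NA` for chapters.
#' @examples
#' icf_parent("d550")   # "d5"
#' icf_parent("b1641")  # "b164"
#' icf_parent("d5")     # NA: chapters are roots
#' @export
icf_parent <- function(code) {
  parse_icf_code(code)
  ndig <- nchar(code) - 1L
  parent_len <- c(`3` = 2L, `4` = 4L, `5` = 5L)[as.character(ndig)]
  out <- rep(NA_character_, length(code))
  has_parent <- !is.na(parent_len)
  out[has_parent] <- substr(code[has_parent], 1L, parent_len[has_parent])
  out
}

#' Build an ICF hierarchy from a set of codes
#'
#' The hierarchy is derived purely from code text (prefix plus digit-count
#' rule); no external taxonomy is needed for the rollups performed here.
#' Unknown-but-well-formed codes (e.g. "other specified" codes such as d5308)
#' are accepted and placed by the same rule.
#'
#' @param codes character vector of ICF codes.
#' @param labels optional named character vector (names = codes) of
#'   human-readable labels; codes without a label default to their own text.
#' @return an object of class `icf_hierarchy`.
#' @export
icf_hierarchy <- function(codes, labels = NULL) {
  codes <- unique(codes)
  parse_icf_code(codes)
  lab <- stats::setNames(codes, codes)
  if (!is.null(labels)) {
    known <- intersect(names(labels), codes)
    lab[known] <- labels[known]
  }
  structure(
    list(codes = codes, parent = stats::setNames(icf_parent(codes), codes),
         labels = lab),
    class = "icf_hierarchy"
  )
}

#' @export
print.icf_hierarchy <- function(x, ...) {
  cat("<icf_hierarchy> ", length(x$codes), " codes, ",
      sum(is.na(x$parent)), " chapter roots\n", sep = "")
  invisible(x)
}

#' Immediate children of a code within a hierarchy
#'
#' @param code a single ICF code present in `hierarchy`.
#' @param hierarchy an [icf_hierarchy()] object.
#' @return character vector of the codes whose parent is `code` (possibly
#'   empty).
#' @examples
#' h <- icf_hierarchy(c("d5", "d540", "d550", "d530", "d5308"))
#' icf_children("d5", h)   # d540, d550, d530
#' icf_children("d530", h) # d5308
#' @export
icf_children <- function(code, hierarchy) {
  stopifnot(inherits(hierarchy, "icf_hierarchy"), length(code) == 1L)
  if (!code %in% hierarchy$codes) {
    stop("code not in hierarchy: ", code, call. = FALSE)
  }
  hierarchy$codes[!is.na(hierarchy$parent) & hierarchy$parent == code]
}

#' Read an optional code-label file
#'
#' One code and label per line, tab-separated. Used only to attach readable
#' labels to hierarchy codes; absent labels default to the code text.
#'
#' @param path path to a tab-separated file with columns code, label.
#' @return named character vector of labels.
#' @export
read_icf_labels <- function(path) {
  df <- utils::read.delim(path, header = FALSE, col.names = c("code", "label"),
                          stringsAsFactors = FALSE)
  parse_icf_code(df$code)
  stats::setNames(df$label, df$code)
}
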
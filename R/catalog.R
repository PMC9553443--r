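# The entity-type catalog: 19 typical entity types of classical Chinese
# medical literature, grouped by the type of book they are characteristic of.
# Where the traditional short labels collide across distinct type names
# (ZZ is used both for "principle of treatment" and "symptoms", FJ for both
# "formula" and "dosis"), the later type in reading order carries a "2"
# suffix so that BIO tag codes stay unique: 19 types, 38 B-/I- tags + "O".

.catalog_table <- function() {
  data.frame(
    name = c(
      "cognitive method", "traditional Chinese physiology",
      "traditional Chinese pathology", "principle of treatment",
      "method of treatment",
      "Chinese materia medica", "symptoms", "pulse", "tongue",
      "formula", "dosis",
      "drug property", "flavor of medicinals", "channel tropism",
      "virtue", "dilantin",
      "pathogeny", "disease", "syndrome"
    ),
    label = c(
      "RSFF", "ZYSL", "ZYBL", "ZZ", "ZF",
      "ZY", "ZZ", "MX", "SX", "FJ", "FJ",
      "YX", "YW", "GJ", "GX", "YM",
      "BY", "JB", "ZH"
    ),
    code = c(
      "RSFF", "ZYSL", "ZYBL", "ZZ", "ZF",
      "ZY", "ZZ2", "MX", "SX", "FJ", "FJ2",
      "YX", "YW", "GJ", "GX", "YM",
      "BY", "JB", "ZH"
    ),
    literature = c(
      rep("canon", 5L), rep("medical_cases", 6L), rep("herbal", 5L),
      rep("comprehensive", 3L)
    ),
    stringsAsFactors = FALSE
  )
}

#' Entity type catalog
#'
#' Returns the catalog of the 19 typical entity types found across four
#' kinds of classical medical literature (canon of medicine, medical cases,
#' herbal, comprehensive), with their short labels.  Each type has a unique
#' \code{code} used in BIO tags (\code{B-<code>} / \code{I-<code>}); the tag
#' space therefore has \eqn{19 \times 2 + 1 = 39} tags.
#'
#' @return object of class \code{entity_catalog}: a data frame with columns
#'   \code{name}, \code{label}, \code{code}, \code{literature}, in fixed row
#'   order, carrying optional per-corpus frequency attributes
#'   (see [count_frequencies()]).
#' @export
entity_catalog <- function() {
  cat <- .catalog_table()
  class(cat) <- c("entity_catalog", "data.frame")
  cat
}

#' @export
print.entity_catalog <- function(x, ...) {
  cat("Entity type catalog:", nrow(x), "types,", 2L * nrow(x) + 1L,
      "BIO tags\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Read or write an entity catalog as JSON
#'
#' The JSON form is a list of records with fields \code{name}, \code{label},
#' \code{code} and \code{literature}.
#'
#' @param path file path.
#' @return \code{read_catalog} returns an \code{entity_catalog}.
#' @export
read_catalog <- function(path) {
  df <- jsonlite::fromJSON(path)
  stopifnot(all(c("name", "label", "code", "literature") %in% names(df)))
  if (anyDuplicated(df$code)) stop("catalog codes must be unique")
  class(df) <- c("entity_catalog", "data.frame")
  df
}

#' @rdname read_catalog
#' @param catalog an \code{entity_catalog}.
#' @export
write_catalog <- function(catalog, path) {
  jsonlite::write_json(as.data.frame(catalog), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

# the full ordered tag set: "O", then B-/I- per catalog row
tag_set <- function(catalog) {
  c("O", as.vector(rbind(paste0("B-", catalog$code),
                         paste0("I-", catalog$code))))
}

# parse one scheme tag into list(prefix, code); validates shape and catalog
parse_tag <- function(tag, catalog) {
  if (tag == "O") return(list(prefix = "O", code = NA_character_))
  if (!grepl("^[BI]-.+$", tag)) stop("malformed tag: ", tag)
  code <- substring(tag, 3L)
  if (!code %in% catalog$code) {
    stop("tag type '", code, "' not in catalog: ", tag)
  }
  list(prefix = substring(tag, 1L, 1L), code = code)
}
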
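# Curated configuration: residue lexicon, engine rule table, MD keywords.
# All three ship as editable YAML under inst/extdata and can be replaced by
# user files of the same schema.

RESIDUE_CATEGORIES <- c("protein", "lipid", "nucleic", "glucid", "water_ions")
ENGINE_LABELS <- c("gromacs", "amber", "namd-charmm", "desmond")

#' Load a residue-name lexicon
#'
#' The lexicon maps residue-name tokens (case-insensitive) to one of the
#' five molecular categories: `protein`, `lipid`, `nucleic`, `glucid`,
#' `water_ions`. Unlisted residues fall into `other`. The YAML schema is one
#' top-level key per category holding a list of tokens.
#'
#' @param path a YAML file; default is the curated lexicon shipped with the
#'   package.
#' @return an object of class `residue_lexicon`: a named character vector,
#'   names are uppercase residue tokens, values are categories.
#' @export
load_residue_lexicon <- function(path = system.file("extdata", "residue_lexicon.yml",
                                                    package = "mdindexr")) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), RESIDUE_CATEGORIES)
  if (length(unknown) > 0L) {
    stop("residue lexicon: unknown categories: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  lex <- stats::setNames(
    unlist(lapply(names(raw), function(cat) rep(cat, length(raw[[cat]])))),
    toupper(unlist(lapply(raw, as.character)))
  )
  if (anyDuplicated(names(lex))) {
    dup <- unique(names(lex)[duplicated(names(lex))])
    stop("residue lexicon: tokens mapped to more than one category: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(lex, class = "residue_lexicon")
}

#' Load the extension -> MD engine rule table
#'
#' Each rule assigns one lowercase file extension (no dot) to one engine
#' label (`gromacs`, `amber`, `namd-charmm`, `desmond`). Rules flagged
#' `requires_keyword` only fire when the dataset metadata matches an MD
#' keyword, because the extension alone is too generic to be trusted. YAML
#' schema: engine -> {extension: requires_keyword flag}.
#'
#' @param path a YAML file; default is the curated table shipped with the
#'   package.
#' @return a data.frame of class `engine_rules` with columns `extension`,
#'   `engine`, `requires_keyword`.
#' @export
load_engine_rules <- function(path = system.file("extdata", "engine_rules.yml",
                                                 package = "mdindexr")) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), ENGINE_LABELS)
  if (length(unknown) > 0L) {
    stop("engine rules: unknown engines: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rows <- do.call(rbind, lapply(names(raw), function(engine) {
    exts <- raw[[engine]]
    data.frame(
      extension = tolower(names(exts)),
      engine = engine,
      requires_keyword = vapply(exts, isTRUE, logical(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
  if (anyDuplicated(rows$extension)) {
    dup <- unique(rows$extension[duplicated(rows$extension)])
    stop("engine rules: duplicated extensions: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  rownames(rows) <- NULL
  class(rows) <- c("engine_rules", "data.frame")
  rows
}

#' Load the MD keyword list
#'
#' Keywords are matched case-insensitively as substrings over a dataset's
#' title + description, both during Explore queries and for keyword-gated
#' engine rules.
#'
#' @param path a YAML file with a top-level `keywords` list; default is the
#'   curated list shipped with the package.
#' @return a character vector of lowercase keywords.
#' @export
load_md_keywords <- function(path = system.file("extdata", "md_keywords.yml",
                                                package = "mdindexr")) {
  raw <- yaml::read_yaml(path)
  kw <- tolower(as.character(raw$keywords %||% character(0)))
  if (length(kw) == 0L) stop("keyword file has no 'keywords' entries", call. = FALSE)
  kw
}

#' Does free-text metadata mention molecular dynamics?
#'
#' @param text character vector (title, description, or their concatenation).
#' @param keywords keyword list from [load_md_keywords()].
#' @return logical vector, `TRUE` where any keyword occurs case-insensitively
#'   as a substring.
#' @export
has_md_keyword <- function(text, keywords = load_md_keywords()) {
  low <- tolower(text)
  low[is.na(low)] <- ""
  Reduce(`|`, lapply(keywords, function(k) grepl(k, low, fixed = TRUE)),
         accumulate = FALSE, right = FALSE,
         init = rep(FALSE, length(low)))
}

#' Extensions trusted to indicate MD content
#'
#' The default trusted-type list used by the cleaning step of the harvest:
#' every extension in the engine rule table that does not require keyword
#' corroboration.
#'
#' @param rules an `engine_rules` table.
#' @return character vector of extensions.
#' @export
trusted_md_extensions <- function(rules = load_engine_rules()) {
  rules$extension[!rules$requires_keyword]
}
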
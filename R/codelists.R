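# Two-part Read CTV3 code lists: five "probable" condition categories and
# four "potential" indicator categories. Matching is exact-string on
# canonical 5-character codes; no terminology-hierarchy expansion.

DD_PROBABLE_CATEGORIES <- c(
  "cerebral_palsy", "down_syndrome", "fragile_x", "asd", "mod_severe_ld"
)
DD_POTENTIAL_CATEGORIES <- c(
  "dev_delay", "gen_dev_disorders", "gen_disabilities", "generic_disability"
)

#' Category names used by the two-part ascertainment strategy
#'
#' The first part ("probable" disability) holds five condition categories;
#' the second ("potential" disability) holds four indicator categories.
#'
#' @param part One of `"all"`, `"probable"`, `"potential"`.
#' @return Character vector of category names.
#' @export
#' @examples
#' disability_categories("probable")
disability_categories <- function(part = c("all", "probable", "potential")) {
  part <- match.arg(part)
  switch(part,
    all = c(DD_PROBABLE_CATEGORIES, DD_POTENTIAL_CATEGORIES),
    probable = DD_PROBABLE_CATEGORIES,
    potential = DD_POTENTIAL_CATEGORIES
  )
}

#' Part (probable/potential) each category belongs to
#'
#' @param category Character vector of category names.
#' @return Character vector, `"probable"` or `"potential"`.
#' @export
category_part <- function(category) {
  bad <- setdiff(category, disability_categories())
  if (length(bad) > 0) {
    stop("unknown category name(s): ", paste(bad, collapse = ", "))
  }
  ifelse(category %in% DD_PROBABLE_CATEGORIES, "probable", "potential")
}

#' Canonicalise Read CTV3 code tokens
#'
#' Read CTV3 codes are 5-character tokens over letters, digits and '.'
#' (a token may begin with '.'). Shorter tokens are right-padded with '.';
#' comparison everywhere in the package is case-sensitive exact-string on
#' the canonical form.
#'
#' @param code Character vector of code tokens.
#' @return Character vector of canonical 5-character codes.
#' @export
#' @examples
#' canonical_read_code(c("F23", "PJ00."))
canonical_read_code <- function(code) {
  code <- trimws(as.character(code))
  if (any(is.na(code) | code == "")) {
    stop("empty Read code token")
  }
  bad <- grepl("[^A-Za-z0-9.]", code)
  if (any(bad)) {
    stop(
      "invalid Read code token(s): ",
      paste(unique(code[bad]), collapse = ", ")
    )
  }
  if (any(nchar(code) > 5)) {
    stop(
      "Read code token longer than 5 characters: ",
      paste(unique(code[nchar(code) > 5]), collapse = ", ")
    )
  }
  n <- nchar(code)
  pad <- strrep(".", 5L - n)
  paste0(code, pad)
}

#' Path to the packaged default code-list file
#'
#' The packaged file transcribes the published two-part lists verbatim,
#' duplicates included, as `category,part,code,description` CSV; the loader
#' collapses duplicates into sets.
#'
#' @return File path.
#' @export
default_codelist_path <- function() {
  system.file("extdata", "read_codelists.csv", package = "ddascertain",
              mustWork = TRUE)
}

#' Load a two-part Read-code list set
#'
#' Reads a `category,part,code,description` CSV, canonicalises codes,
#' checks category/part consistency and collapses within-category
#' duplicates into sets (the raw transcription is retained for validation
#' reporting).
#'
#' @param path Code-list CSV path; defaults to the packaged lists.
#' @return A `codelist_set`: list with `entries` (named list of unique
#'   canonical codes per category), `raw` (the transcription as read, with
#'   line numbers) and `provenance`.
#' @export
#' @examples
#' cls <- load_codelists()
#' lengths(cls$entries)[disability_categories("potential")]
load_codelists <- function(path = default_codelist_path()) {
  if (!file.exists(path)) {
    stop("code-list file not found: ", path)
  }
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  needed <- c("category", "part", "code")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("code-list file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"description" %in% names(raw)) raw$description <- ""
  raw$line <- seq_len(nrow(raw)) + 1L  # data line numbers (header is line 1)

  if (nrow(raw) > 0) {
    blank <- raw$category == "" | raw$part == "" | raw$code == ""
    if (any(blank)) {
      stop("malformed code-list row at line ",
           paste(raw$line[blank], collapse = ", "),
           ": category, part and code are all required")
    }
    unknown <- !raw$category %in% disability_categories()
    if (any(unknown)) {
      stop("unknown category name(s) in ", path, ": ",
           paste(unique(raw$category[unknown]), collapse = ", "),
           " (line ", paste(raw$line[unknown], collapse = ", "), ")")
    }
    wrong_part <- raw$part != category_part(raw$category)
    if (any(wrong_part)) {
      stop("part/category mismatch at line ",
           paste(raw$line[wrong_part], collapse = ", "))
    }
    raw$code <- canonical_read_code(raw$code)
  }

  entries <- lapply(disability_categories(), function(cat) {
    unique(raw$code[raw$category == cat])
  })
  names(entries) <- disability_categories()

  structure(
    list(entries = entries, raw = raw, provenance = path),
    class = "codelist_set"
  )
}

#' Write a code-list set to CSV
#'
#' Writes the deduplicated entries in the `category,part,code,description`
#' schema; reloading the written file reproduces identical entries.
#'
#' @param cls A `codelist_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_codelists <- function(cls, path) {
  stopifnot(inherits(cls, "codelist_set"))
  rows <- do.call(rbind, lapply(names(cls$entries), function(cat) {
    codes <- cls$entries[[cat]]
    if (length(codes) == 0) return(NULL)
    desc <- cls$raw$description[match(codes, cls$raw$code)]
    desc[is.na(desc)] <- ""
    data.frame(category = cat, part = category_part(cat), code = codes,
               description = desc, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(category = character(), part = character(),
                       code = character(), description = character())
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Validate a code-list set
#'
#' Reports, without mutating the set, every within-category duplicate in
#' the raw transcription and every code present in both a probable and a
#' potential category. The published condition table contains both kinds
#' of anomaly, so raw and unique counts are reported side by side.
#'
#' @param cls A `codelist_set`.
#' @return A `codelist_validation`: raw and unique entry counts per
#'   category, a duplicate table and the cross-part overlap codes.
#' @export
validate_codelists <- function(cls) {
  stopifnot(inherits(cls, "codelist_set"))
  cats <- disability_categories()
  raw_n <- vapply(cats, function(cat) sum(cls$raw$category == cat), 0L)
  uniq_n <- vapply(cls$entries[cats], length, 0L)

  dup_rows <- do.call(rbind, lapply(cats, function(cat) {
    codes <- cls$raw$code[cls$raw$category == cat]
    tab <- table(codes)
    dup <- tab[tab > 1]
    if (length(dup) == 0) return(NULL)
    data.frame(code = names(dup), category = cat, times = as.integer(dup),
               stringsAsFactors = FALSE)
  }))
  if (is.null(dup_rows)) {
    dup_rows <- data.frame(code = character(), category = character(),
                           times = integer())
  }

  probable_codes <- unique(unlist(cls$entries[DD_PROBABLE_CATEGORIES],
                                  use.names = FALSE))
  potential_codes <- unique(unlist(cls$entries[DD_POTENTIAL_CATEGORIES],
                                   use.names = FALSE))
  overlap <- sort(intersect(probable_codes, potential_codes))

  structure(
    list(
      raw_entry_count = raw_n,
      unique_count = uniq_n,
      within_category_duplicates = dup_rows,
      cross_part_overlaps = overlap,
      total_raw = c(probable = sum(raw_n[DD_PROBABLE_CATEGORIES]),
                    potential = sum(raw_n[DD_POTENTIAL_CATEGORIES])),
      total_unique = c(probable = length(probable_codes),
                       potential = length(potential_codes))
    ),
    class = "codelist_validation"
  )
}

#' @export
print.codelist_validation <- function(x, ...) {
  cat("Two-part code-list validation\n")
  cat(sprintf("  probable part : %d raw entries, %d unique codes\n",
              x$total_raw[["probable"]], x$total_unique[["probable"]]))
  cat(sprintf("  potential part: %d raw entries, %d unique codes\n",
              x$total_raw[["potential"]], x$total_unique[["potential"]]))
  for (cat_ in names(x$raw_entry_count)) {
    cat(sprintf("    %-18s raw %3d  unique %3d\n", cat_,
                x$raw_entry_count[[cat_]], x$unique_count[[cat_]]))
  }
  if (nrow(x$within_category_duplicates) > 0) {
    cat(sprintf("  %d within-category duplicate code(s)\n",
                nrow(x$within_category_duplicates)))
  }
  if (length(x$cross_part_overlaps) > 0) {
    cat("  cross-part overlaps:",
        paste(x$cross_part_overlaps, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.codelist_set <- function(x, ...) {
  cat("codelist_set:", sum(lengths(x$entries)), "unique codes in",
      sum(lengths(x$entries) > 0), "categories\n")
  cat("  source:", x$provenance, "\n")
  invisible(x)
}

#' Categories containing a Read code
#'
#' @param code A single Read code token (canonicalised before lookup).
#' @param cls A `codelist_set`.
#' @return Character vector of category names containing the code
#'   (possibly spanning both parts); empty for an unlisted code.
#' @export
#' @examples
#' categories_for("PJ00.", load_codelists())
categories_for <- function(code, cls) {
  stopifnot(inherits(cls, "codelist_set"), length(code) == 1)
  code <- canonical_read_code(code)
  hit <- vapply(cls$entries, function(codes) code %in% codes, logical(1))
  names(cls$entries)[hit]
}

# Long lookup table code -> (category, part), one row per membership.
codelist_lookup <- function(cls) {
  stopifnot(inherits(cls, "codelist_set"))
  cats <- names(cls$entries)
  n <- lengths(cls$entries)
  data.frame(
    code = unlist(cls$entries, use.names = FALSE),
    category = rep(cats, n),
    part = rep(category_part(cats), n),
    stringsAsFactors = FALSE
  )
}
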
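#' Read a GMT pathway catalog
#'
#' Each GMT line holds a set name, a description, and tab-separated member
#' genes. Duplicate members within a record are deduplicated; records with no
#' members are an error naming the offending line.
#'
#' @param path path to a GMT file.
#' @return named list of character member vectors, with a `description`
#'   attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- list()
  desc <- character()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    members <- unique(p[-(1:2)][nzchar(p[-(1:2)])])
    if (length(p) < 3 || !length(members))
      stop("GMT record with empty member list at line ", i, ": ", p[1])
    out[[p[1]]] <- members
    desc[p[1]] <- p[2]
  }
  attr(out, "description") <- desc
  out
}

#' Write a GMT pathway catalog
#'
#' @param catalog named list of member vectors.
#' @param path output path.
#' @param descriptions optional named descriptions (defaults to the set name).
#' @export
write_gmt <- function(catalog, path, descriptions = NULL) {
  lines <- vapply(names(catalog), function(nm) {
    members <- unique(catalog[[nm]])
    if (!length(members)) stop("refusing to write empty GMT record: ", nm)
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else nm
    paste(c(nm, d, members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a gene set catalog as 30 GMT records
#'
#' One record per gene set and subset, named `set [up]`, `set [down]`,
#' `set [up+down]`. Empty subsets are skipped.
#'
#' @param sets a `gene_set_catalog`.
#' @param path output GMT path.
#' @export
catalog_to_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_catalog"))
  records <- list()
  for (nm in names(sets)) {
    entry <- sets[[nm]]
    for (sub in c("up", "down", "up+down")) {
      members <- if (sub == "up+down") entry$members else entry[[sub]]
      if (length(members))
        records[[sprintf("%s [%s]", nm, sub)]] <- members
    }
  }
  write_gmt(records, path)
}

#' Write a data frame as TSV (the package's tabular dialect)
#'
#' UTF-8, header row, tab separated, "." for missing.
#'
#' @param x data frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
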
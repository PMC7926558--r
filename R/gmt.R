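#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `set_name  description  member1  member2 ...`. Duplicate members within a
#' set are removed; duplicate set names are an error.
#'
#' @param path path to the GMT file.
#' @return A named list of character vectors (class `gene_set_collection`);
#'   set descriptions are kept in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("GMT file is empty: ", path)
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("GMT format error at line %d: need set name, description and >=1 member", i))
    }
    nm <- f[[1]]
    if (nm %in% names(sets)) stop("duplicate gene set name: ", nm)
    sets[[nm]] <- unique(f[-(1:2)])
    desc[[nm]] <- f[[2]]
  }
  structure(sets, description = desc, class = c("gene_set_collection", "list"))
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional named character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(description) && nm %in% names(description)) description[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
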
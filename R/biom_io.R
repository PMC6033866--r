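#' Write an epiallele count table as BIOM JSON
#'
#' Serialises the sample-by-epiallele table in the BIOM v1 (JSON) dialect
#' with epiallele patterns as observations and specimens as samples, the
#' interchange format of the diversity toolchain. Table provenance
#' (locus, rarefaction depth and seed) is carried in the BIOM `id` field.
#' The empty table (zero patterns) is written as a valid degenerate file.
#'
#' @param table An [epiallele_count_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_biom_table()]
#' @export
write_biom_table <- function(table, path) {
  stopifnot(inherits(table, "epiallele_count_table"))
  id <- jsonlite::toJSON(list(locus_name = table$locus_name,
                              n_cpg = table$n_cpg,
                              rarefaction_depth = table$rarefaction_depth,
                              seed = table$seed),
                         auto_unbox = TRUE, null = "null")
  if (ncol(table$counts) == 0L) {
    # biomformat cannot represent a 0-observation matrix; emit the
    # degenerate BIOM v1 document directly
    doc <- list(
      id = as.character(id), format = "Biological Observation Matrix 1.0.0",
      format_url = "http://biom-format.org",
      type = "OTU table", generated_by = "epidiv",
      date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      matrix_type = "dense", matrix_element_type = "int",
      shape = c(0L, nrow(table$counts)),
      rows = list(),
      columns = lapply(rownames(table$counts),
                       function(s) list(id = s, metadata = NULL)),
      data = list()
    )
    writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                                digits = NA), path)
  } else {
    b <- biomformat::make_biom(t(table$counts), id = as.character(id))
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Read an epiallele count table from BIOM JSON
#'
#' Inverse of [write_biom_table()]: counts, sample order, pattern order
#' and the provenance metadata round-trip exactly.
#'
#' @param path Path to a BIOM v1 JSON file written by this package.
#' @return An [epiallele_count_table()].
#' @export
read_biom_table <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed BIOM file '", path, "': ",
                                           conditionMessage(e)))
  for (field in c("rows", "columns", "data", "shape"))
    if (is.null(doc[[field]]))
      stop("malformed BIOM file '", path, "': missing field '", field, "'")
  meta <- tryCatch(jsonlite::fromJSON(doc$id %||% "{}"),
                   error = function(e) list())
  samples <- vapply(doc$columns, function(cc) cc$id, "")
  patterns <- vapply(doc$rows, function(rr) rr$id, "")
  counts <- matrix(0L, length(samples), length(patterns),
                   dimnames = list(samples, patterns))
  if (length(patterns)) {
    b <- biomformat::read_biom(path)
    # observations x samples, in file order (dimnames are unreliable for
    # single-sample tables, so order is taken from the document itself)
    dat <- as.matrix(biomformat::biom_data(b))
    if (nrow(dat) != length(patterns) || ncol(dat) != length(samples))
      stop("malformed BIOM file '", path, "': shape does not match rows/columns")
    counts[] <- t(dat)
  }
  epiallele_count_table(counts,
                        locus_name = meta$locus_name %||% "locus",
                        rarefaction_depth = meta$rarefaction_depth,
                        seed = meta$seed,
                        n_cpg = meta$n_cpg)
}
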
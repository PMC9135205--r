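#' Read and write genome-architecture files
#'
#' Architectures are stored as YAML (default) or JSON with top-level keys
#' `genes` (list of `{name, length}` records in genome order), `elements`
#' (list of `{kind, region, strength}` records) and `spacer_length`. The
#' format is chosen from the file extension (`.json` for JSON, anything
#' else YAML). Reading validates the file against the genome invariants
#' and names the offending record on failure; `read_architecture()` and
#' `write_architecture()` are exact inverses.
#'
#' @param path File path.
#' @param genome A `genome_architecture`.
#' @param defaults Element defaults used for bounds validation on read.
#' @return `read_architecture()` returns a `genome_architecture`;
#'   `write_architecture()` returns `path` invisibly.
#' @export
read_architecture <- function(path, defaults = element_defaults()) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  architecture_from_list(raw, defaults)
}

architecture_from_list <- function(raw, defaults = element_defaults()) {
  if (is.null(raw$genes) || length(raw$genes) == 0)
    stop("architecture file must list at least one gene")
  genes <- data.frame(
    name = vapply(raw$genes, function(g) as.character(g$name), ""),
    length = vapply(raw$genes, function(g) as.integer(g$length), 1L),
    stringsAsFactors = FALSE
  )
  elements <- if (length(raw$elements) > 0) {
    data.frame(
      kind = vapply(raw$elements, function(e) as.character(e$kind), ""),
      region = vapply(raw$elements, function(e) as.integer(e$region), 1L),
      strength = vapply(raw$elements, function(e) as.numeric(e$strength), 1),
      stringsAsFactors = FALSE
    )
  } else {
    empty_elements()
  }
  spacer <- if (is.null(raw$spacer_length)) 50L else as.integer(raw$spacer_length)
  genome_architecture(genes, elements, spacer, defaults)
}

#' @rdname read_architecture
#' @export
write_architecture <- function(genome, path) {
  validate_genome(genome)
  out <- architecture_to_list(genome)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(out, path, precision = 15)
  }
  invisible(path)
}

architecture_to_list <- function(genome) {
  el <- canonical_elements(genome$elements)
  list(
    genes = lapply(seq_len(nrow(genome$genes)), function(i)
      list(name = genome$genes$name[i],
           length = genome$genes$length[i])),
    elements = lapply(seq_len(nrow(el)), function(i)
      list(kind = el$kind[i], region = el$region[i],
           strength = el$strength[i])),
    spacer_length = genome$spacer_length
  )
}
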
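#' Regulatory element kinds
#'
#' Element kinds recognised by the genome model, in their fixed 5'->3'
#' order within a regulatory region: a terminator ends transcripts arriving
#' from upstream before the region's promoter, and the RNase cleavage site
#' lies downstream of the promoter so that it falls inside transcripts
#' initiated at the co-located promoter.
#'
#' @return Character vector of the three element kinds.
#' @export
element_kinds <- function() {
  c("terminator", "promoter", "rnase_site")
}

#' Default insertion strengths and bounds for regulatory elements
#'
#' Insertion defaults and hard bounds for each element kind: promoters are
#' inserted at a binding-rate constant of 1e6 (bounds 1e5 to 1e13), RNase
#' cleavage sites at a cleavage-rate constant of 5e-3 (bounds 0 to 1), and
#' terminators at a termination probability of 0.2 (bounds 0 to 1).
#'
#' @return Named list with one entry per element kind, each a list with
#'   components `insert`, `min`, `max`.
#' @export
element_defaults <- function() {
  list(
    promoter   = list(insert = 1e6,  min = 1e5, max = 1e13),
    terminator = list(insert = 0.2,  min = 0,   max = 1),
    rnase_site = list(insert = 5e-3, min = 0,   max = 1)
  )
}

#' Construct a genome architecture
#'
#' A genome architecture is the evolvable genotype: an ordered set of
#' protein-coding genes laid out on a single strand, separated by fixed
#' length regulatory regions (spacers), plus a set of regulatory elements
#' (promoters, terminators, RNase cleavage sites) each assigned to one
#' region with a strength. For M genes there are M + 1 regions: region 0
#' lies upstream of gene 1, region i between genes i and i + 1, and region
#' M downstream of the last gene. At most one element of each kind may
#' occupy a region.
#'
#' @param genes Data frame with columns `name` (unique identifiers) and
#'   `length` (nucleotides, > 0), in genome order.
#' @param elements Data frame with columns `kind` (one of
#'   [element_kinds()]), `region` (integer in 0..M) and `strength`
#'   (numeric). May have zero rows.
#' @param spacer_length Nucleotides per regulatory region (default 50).
#' @param defaults Strength bounds used for validation; see
#'   [element_defaults()].
#' @return An object of class `genome_architecture`.
#' @export
genome_architecture <- function(genes, elements = empty_elements(),
                                spacer_length = 50,
                                defaults = element_defaults()) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!all(c("name", "length") %in% names(genes)))
    stop("`genes` must have columns `name` and `length`")
  if (nrow(genes) < 1) stop("at least one gene is required")
  genes$name <- as.character(genes$name)
  genes$length <- as.integer(genes$length)
  if (anyDuplicated(genes$name)) stop("gene names must be unique")
  if (any(genes$length <= 0)) stop("gene lengths must be positive")
  if (!is.numeric(spacer_length) || spacer_length < 5)
    stop("`spacer_length` must be at least 5 nucleotides")

  elements <- as.data.frame(elements, stringsAsFactors = FALSE)
  if (nrow(elements) > 0) {
    if (!all(c("kind", "region", "strength") %in% names(elements)))
      stop("`elements` must have columns `kind`, `region`, `strength`")
    elements$kind <- as.character(elements$kind)
    elements$region <- as.integer(elements$region)
    elements$strength <- as.numeric(elements$strength)
  } else {
    elements <- empty_elements()
  }

  g <- structure(
    list(genes = genes[, c("name", "length")],
         elements = canonical_elements(elements),
         spacer_length = as.integer(spacer_length)),
    class = "genome_architecture"
  )
  validate_genome(g, defaults)
  g
}

empty_elements <- function() {
  data.frame(kind = character(), region = integer(),
             strength = numeric(), stringsAsFactors = FALSE)
}

# Canonical element order: by region, then by within-region 5'->3' kind
# order. Makes serialization and fingerprints stable.
canonical_elements <- function(elements) {
  if (nrow(elements) == 0) return(empty_elements())
  ord <- order(elements$region, match(elements$kind, element_kinds()))
  el <- elements[ord, c("kind", "region", "strength"), drop = FALSE]
  rownames(el) <- NULL
  el
}

validate_genome <- function(genome, defaults = element_defaults()) {
  el <- genome$elements
  m <- n_genes(genome)
  if (nrow(el) == 0) return(invisible(genome))
  bad_kind <- setdiff(el$kind, element_kinds())
  if (length(bad_kind) > 0)
    stop("unknown element kind: ", paste(bad_kind, collapse = ", "))
  if (any(el$region < 0 | el$region > m))
    stop("element region out of range 0..", m)
  key <- paste(el$kind, el$region)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate element in region (only one of each kind per region): ",
         dup)
  }
  for (i in seq_len(nrow(el))) {
    b <- defaults[[el$kind[i]]]
    if (el$strength[i] < b$min || el$strength[i] > b$max)
      stop(sprintf("strength %g of %s in region %d outside bounds [%g, %g]",
                   el$strength[i], el$kind[i], el$region[i], b$min, b$max))
  }
  invisible(genome)
}

#' @export
print.genome_architecture <- function(x, ...) {
  cat(sprintf("Genome architecture: %d genes, %d regulatory elements\n",
              n_genes(x), nrow(x$elements)))
  cat(sprintf("  genome length %d nt (spacer %d nt, %d regions)\n",
              genome_length(x), x$spacer_length, n_genes(x) + 1L))
  if (nrow(x$elements) > 0) {
    for (i in seq_len(nrow(x$elements)))
      cat(sprintf("  %-10s region %d  strength %g\n",
                  x$elements$kind[i], x$elements$region[i],
                  x$elements$strength[i]))
  }
  invisible(x)
}

#' @export
format.genome_architecture <- function(x, ...) fingerprint(x)

#' Number of genes in an architecture
#' @param genome A `genome_architecture`.
#' @return Integer gene count.
#' @export
n_genes <- function(genome) nrow(genome$genes)

#' Total genome length
#'
#' Genome length in nucleotides: M gene lengths plus M + 1 spacers.
#'
#' @param genome A `genome_architecture`.
#' @return Integer length in nucleotides.
#' @export
genome_length <- function(genome) {
  sum(genome$genes$length) + (n_genes(genome) + 1L) * genome$spacer_length
}

#' Genome coordinates of genes and regulatory regions
#'
#' Computes 1-based inclusive coordinates of every gene and spacer from the
#' gene lengths and the spacer length. Layout is
#' `spacer_0, gene_1, spacer_1, ..., gene_M, spacer_M`.
#'
#' @param genome A `genome_architecture`.
#' @return List with data frames `genes` (name, start, end) and `regions`
#'   (region, start, end).
#' @export
genome_coordinates <- function(genome) {
  s <- genome$spacer_length
  m <- n_genes(genome)
  lens <- genome$genes$length
  gene_start <- integer(m)
  pos <- 0L
  regions <- data.frame(region = 0:m, start = NA_integer_, end = NA_integer_)
  for (i in 0:m) {
    regions$start[i + 1L] <- pos + 1L
    regions$end[i + 1L] <- pos + s
    pos <- pos + s
    if (i < m) {
      gene_start[i + 1L] <- pos + 1L
      pos <- pos + lens[i + 1L]
    }
  }
  list(
    genes = data.frame(name = genome$genes$name, start = gene_start,
                       end = gene_start + lens - 1L,
                       stringsAsFactors = FALSE),
    regions = regions
  )
}

# Point positions of elements within their region. Fixed fractional
# offsets preserve the within-region 5'->3' order
# terminator < promoter < rnase_site for any spacer >= 5 nt.
element_positions <- function(genome) {
  el <- genome$elements
  if (nrow(el) == 0)
    return(cbind(el, data.frame(position = integer())))
  s <- genome$spacer_length
  offs <- c(terminator = ceiling(0.3 * s), promoter = ceiling(0.5 * s),
            rnase_site = ceiling(0.8 * s))
  regions <- genome_coordinates(genome)$regions
  el$position <- regions$start[match(el$region, regions$region)] +
    as.integer(offs[el$kind]) - 1L
  el
}

#' Starting genome for evolutionary runs
#'
#' The canonical starting genotype: `n_genes` protein-coding genes of
#' `gene_length` nucleotides each, with a single moderate-strength promoter
#' in region 0 (upstream of the first gene) at the promoter insertion
#' default, and no other regulatory elements.
#'
#' @param n_genes Number of genes (>= 1).
#' @param defaults Element defaults; the starting promoter uses
#'   `defaults$promoter$insert`.
#' @param gene_length Length of every gene in nucleotides (default 150).
#' @param spacer_length Regulatory region length (default 50).
#' @return A `genome_architecture`.
#' @export
make_starting_genome <- function(n_genes, defaults = element_defaults(),
                                 gene_length = 150, spacer_length = 50) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1)
    stop("`n_genes` must be a single integer >= 1")
  n_genes <- as.integer(n_genes)
  genome_architecture(
    genes = data.frame(name = paste0("gene", seq_len(n_genes)),
                       length = gene_length),
    elements = data.frame(kind = "promoter", region = 0L,
                          strength = defaults$promoter$insert),
    spacer_length = spacer_length,
    defaults = defaults
  )
}

#' Positive-control genome architecture
#'
#' A known three-gene architecture used to generate positive-control
#' targets: promoters upstream of genes 1 and 2 (regions 0 and 1),
#' terminators after genes 2 and 3 (regions 2 and 3), and an RNase
#' cleavage site between the second promoter and gene 2 (region 1). All
#' elements sit at their insertion-default strengths. Because a simulation
#' of this genome generates the target, an exact genetic solution to that
#' target is guaranteed to exist.
#'
#' @param defaults Element defaults supplying the strengths.
#' @return A `genome_architecture` with three genes.
#' @export
positive_control_genome <- function(defaults = element_defaults()) {
  genome_architecture(
    genes = data.frame(name = c("geneX", "geneY", "geneZ"), length = 150),
    elements = data.frame(
      kind = c("promoter", "promoter", "rnase_site", "terminator",
               "terminator"),
      region = c(0L, 1L, 1L, 2L, 3L),
      strength = c(defaults$promoter$insert, defaults$promoter$insert,
                   defaults$rnase_site$insert, defaults$terminator$insert,
                   defaults$terminator$insert)
    ),
    defaults = defaults
  )
}

#' Add, remove or retune a regulatory element
#'
#' Helpers returning a modified copy of the genome. `add_element()` fails
#' if the (kind, region) slot is occupied; `remove_element()` and
#' `set_element_strength()` fail if it is empty.
#'
#' @param genome A `genome_architecture`.
#' @param kind Element kind; see [element_kinds()].
#' @param region Region index in 0..M.
#' @param strength New strength (for add, defaults to the kind's insertion
#'   default).
#' @param defaults Element defaults for bounds checking.
#' @return The modified `genome_architecture`.
#' @export
add_element <- function(genome, kind, region, strength = NULL,
                        defaults = element_defaults()) {
  if (is.null(strength)) strength <- defaults[[kind]]$insert
  el <- rbind(genome$elements,
              data.frame(kind = kind, region = as.integer(region),
                         strength = strength, stringsAsFactors = FALSE))
  genome$elements <- canonical_elements(el)
  validate_genome(genome, defaults)
  genome
}

#' @rdname add_element
#' @export
remove_element <- function(genome, kind, region) {
  idx <- element_index(genome, kind, region)
  genome$elements <- canonical_elements(genome$elements[-idx, , drop = FALSE])
  genome
}

#' @rdname add_element
#' @export
set_element_strength <- function(genome, kind, region, strength,
                                 defaults = element_defaults()) {
  idx <- element_index(genome, kind, region)
  genome$elements$strength[idx] <- strength
  validate_genome(genome, defaults)
  genome
}

element_index <- function(genome, kind, region) {
  idx <- which(genome$elements$kind == kind &
                 genome$elements$region == region)
  if (length(idx) != 1)
    stop(sprintf("no %s element in region %d", kind, region))
  idx
}

#' Architecture fingerprint
#'
#' Canonical presence/absence signature of a genome's regulatory elements:
#' the sorted (kind, region) pairs, ignoring strengths. Two genomes that
#' differ only in element strengths have identical fingerprints. The
#' fingerprint is the unit counted in diversity analyses.
#'
#' @param genome A `genome_architecture`.
#' @return A single string, e.g. `"promoter@0|rnase_site@1"`; `""` for a
#'   genome without elements.
#' @export
fingerprint <- function(genome) {
  el <- genome$elements
  if (nrow(el) == 0) return("")
  ord <- order(el$region, match(el$kind, element_kinds()))
  paste(sprintf("%s@%d", el$kind[ord], el$region[ord]), collapse = "|")
}
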
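#' Classify cytosines of an amplicon sequence by dinucleotide context
#'
#' Every internal cytosine (i.e. every C that is not the terminal base) is
#' assigned exactly one context: CpG if the following base is G, otherwise
#' CpH with H recorded as A, C or T. A terminal C has no observable
#' downstream base and is excluded from both inventories.
#'
#' @param sequence A single uppercase DNA string over the alphabet A/C/G/T.
#'   Lowercase letters and IUPAC ambiguity codes are rejected: the top
#'   bisulfite strand is modelled explicitly and orientation is resolved at
#'   alignment time, not here.
#' @return A list with components `cpg_positions` and `cph_positions`
#'   (1-based indices of the C), `cph_context` (character vector "CpA",
#'   "CpC" or "CpT", parallel to `cph_positions`), and counts `n_cpg`,
#'   `n_cph`.
#' @examples
#' classify_cytosines("ACGTCAC")
#' @export
classify_cytosines <- function(sequence) {
  chars <- .check_dna(sequence)
  n <- length(chars)
  c_idx <- which(chars == "C")
  c_idx <- c_idx[c_idx < n]               # terminal C: context unknown
  nxt <- chars[c_idx + 1L]
  cpg <- c_idx[nxt == "G"]
  cph <- c_idx[nxt != "G"]
  ctx <- paste0("Cp", chars[cph + 1L])
  list(
    cpg_positions = cpg,
    cph_positions = cph,
    cph_context   = ctx,
    n_cpg         = length(cpg),
    n_cph         = length(cph)
  )
}

#' In-silico bisulfite conversion of a reference sequence
#'
#' With `preserve_cpg = FALSE` all cytosines become T: the fully converted
#' (fully unmethylated) reference that reads are aligned against. With
#' `preserve_cpg = TRUE` CpG cytosines are emitted as the degenerate base Y
#' (matches C or T, i.e. methylation state unknown) while CpH and terminal
#' cytosines become T.
#'
#' @param sequence Uppercase A/C/G/T string.
#' @param preserve_cpg Keep CpG cytosines as the ambiguity code Y?
#' @return The converted sequence as a single string.
#' @examples
#' bisulfite_convert("ACGTC")                      # "ATGTT"
#' bisulfite_convert("ACGTC", preserve_cpg = TRUE) # "AYGTT"
#' @export
bisulfite_convert <- function(sequence, preserve_cpg = FALSE) {
  chars <- .check_dna(sequence)
  out <- chars
  out[out == "C"] <- "T"
  if (preserve_cpg) {
    cls <- classify_cytosines(sequence)
    out[cls$cpg_positions] <- "Y"
  }
  paste(out, collapse = "")
}

#' TSS-relative coordinate labels
#'
#' Amplicon coordinates are given relative to the transcriptional start
#' site: +1 is the first transcribed base and there is no position 0, so
#' the label sequence runs ..., -2, -1, +1, +2, .... Under this convention
#' an amplicon spanning -a/+b contains a + b bases.
#'
#' @param index 1-based position(s) within the amplicon sequence.
#' @param tss_offset 1-based index of the base whose label is +1.
#' @return Integer label(s); negative upstream of the TSS, positive from it.
#' @seealso [tss_index()] for the inverse, [tss_span()] for span lengths.
#' @export
tss_label <- function(index, tss_offset) {
  stopifnot(is.numeric(index), is.numeric(tss_offset), length(tss_offset) == 1L)
  if (any(index < 1L))
    stop("index out of range: positions are 1-based")
  index <- as.integer(index)
  ifelse(index >= tss_offset, index - tss_offset + 1L, index - tss_offset)
}

#' @rdname tss_label
#' @param label signed TSS-relative label(s), zero excluded.
#' @export
tss_index <- function(label, tss_offset) {
  stopifnot(is.numeric(label), length(tss_offset) == 1L)
  if (any(label == 0L)) stop("TSS-relative label 0 does not exist")
  label <- as.integer(label)
  ifelse(label > 0L, tss_offset + label - 1L, tss_offset + label)
}

#' @rdname tss_label
#' @param from,to signed TSS-relative labels delimiting a span (inclusive).
#' @return `tss_span()`: the number of bases between two labels.
#' @examples
#' tss_span(-104, 221) # 325
#' tss_span(-330, 104) # 434
#' @export
tss_span <- function(from, to) {
  stopifnot(from != 0L, to != 0L, from <= to)
  as.integer((to - from + 1) - (from < 0 && to > 0))
}

#' Construct an amplicon reference
#'
#' Bundles a locus's sequence with its TSS anchor and the classified
#' cytosine inventory. All downstream stages (read alignment, profile
#' calling, methylation summaries) consume this object.
#'
#' @param locus_name Character scalar.
#' @param sequence Uppercase A/C/G/T amplicon sequence (top bisulfite
#'   strand as targeted by the primers).
#' @param tss_offset 1-based index of the +1 base. May lie outside the
#'   sequence for amplicons that do not cross the TSS.
#' @param strand_note Free-text note on which bisulfite strand the primers
#'   target.
#' @param is_unmethylated_control `TRUE` for a spike-in reference (e.g. an
#'   M13mp18-like fully unmethylated control): every cytosine of reads
#'   derived from it is expected to read as T after conversion.
#' @param primer_mask Optional integer vector of 1-based positions (primer
#'   annealing regions) whose CpG sites are dropped from `cpg_positions`.
#' @return An object of class `amplicon_reference`: list with the fields
#'   above plus `cpg_positions`, `cph_positions`, `cph_context`,
#'   `cpg_labels`/`cph_labels` (TSS-relative), `n_cpg`, `n_cph`, `length`.
#' @export
amplicon_reference <- function(locus_name, sequence, tss_offset,
                               strand_note = "bisulfite top strand",
                               is_unmethylated_control = FALSE,
                               primer_mask = NULL) {
  stopifnot(is.character(locus_name), length(locus_name) == 1L, nzchar(locus_name))
  chars <- .check_dna(sequence)
  cls <- classify_cytosines(sequence)
  if (!is.null(primer_mask)) {
    primer_mask <- as.integer(primer_mask)
    cls$cpg_positions <- setdiff(cls$cpg_positions, primer_mask)
    cls$n_cpg <- length(cls$cpg_positions)
  }
  ref <- list(
    locus_name = locus_name,
    sequence = paste(chars, collapse = ""),
    length = length(chars),
    tss_offset = as.integer(tss_offset),
    strand_note = strand_note,
    is_unmethylated_control = isTRUE(is_unmethylated_control),
    cpg_positions = cls$cpg_positions,
    cph_positions = cls$cph_positions,
    cph_context = cls$cph_context,
    n_cpg = cls$n_cpg,
    n_cph = cls$n_cph,
    cpg_labels = tss_label(cls$cpg_positions, tss_offset),
    cph_labels = tss_label(cls$cph_positions, tss_offset)
  )
  class(ref) <- "amplicon_reference"
  ref
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat(sprintf("amplicon_reference '%s': %d bp, %d CpG, %d CpH%s\n",
              x$locus_name, x$length, x$n_cpg, x$n_cph,
              if (x$is_unmethylated_control) " [unmethylated spike-in control]" else ""))
  if (x$n_cpg > 0L)
    cat("  CpG sites (TSS-relative): ",
        paste(sprintf("%+d", x$cpg_labels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read amplicon references from FASTA with a sidecar configuration
#'
#' The FASTA holds one record per locus; the configuration (a YAML file or
#' an equivalent named list) supplies the TSS offset and control flag per
#' record, keyed by FASTA record name.
#'
#' @param fasta_path Path to the reference FASTA.
#' @param config Named list (or path to a YAML file) mapping each record
#'   name to a list with `tss_offset` and optionally
#'   `is_unmethylated_control`, `strand_note`.
#' @return Named list of [amplicon_reference()] objects.
#' @export
read_amplicon_references <- function(fasta_path, config) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  nm <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(nm, names(config))
  if (length(missing))
    stop("no configuration entry for FASTA record(s): ", paste(missing, collapse = ", "))
  refs <- lapply(seq_along(seqs), function(i) {
    cf <- config[[nm[i]]]
    amplicon_reference(
      locus_name = nm[i],
      sequence = as.character(seqs[[i]]),
      tss_offset = cf$tss_offset,
      strand_note = cf$strand_note %||% "bisulfite top strand",
      is_unmethylated_control = isTRUE(cf$is_unmethylated_control)
    )
  })
  names(refs) <- nm
  refs
}

# validate and split a DNA string; reports the first offending position
.check_dna <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop(sprintf("non-ACGT character '%s' at position %d (uppercase A/C/G/T only)",
                 chars[bad[1]], bad[1]))
  chars
}

`%||%` <- function(a, b) if (is.null(a)) b else a
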
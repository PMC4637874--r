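# Alignment container and I/O. Sequences are stored as an integer state
# matrix (taxa x columns) over the 20 amino acids or the 61 sense codons;
# gaps and ambiguities are NA (missing data, marginalized in the likelihood).

#' Read a multiple sequence alignment
#'
#' Reads FASTA or relaxed sequential PHYLIP into a `phylo_alignment`.
#' In `"aa"` mode each column is one residue; gaps (`-`, `.`) and ambiguity
#' codes (`X`, `B`, `Z`, `J`, `U`, `O`, `?`, `*`) become missing data. In
#' `"codon"` mode the nucleotide alignment is grouped into in-frame triplets;
#' any triplet containing a gap or ambiguity becomes missing, and in-frame
#' stop codons are an error.
#'
#' @param path Input file (FASTA unless `format = "phylip"`).
#' @param alphabet `"aa"` or `"codon"`.
#' @param format `"fasta"` or `"phylip"`.
#' @param ref_taxon Optional reference taxon name used for position
#'   reporting; defaults to the first sequence.
#' @return A `phylo_alignment`: integer state matrix `x` (taxa by columns,
#'   `NA` = missing), `taxa`, `alphabet`, `L` columns, and `states`.
#' @export
read_alignment <- function(path, alphabet = c("aa", "codon"),
                           format = c("fasta", "phylip"), ref_taxon = NULL) {
  alphabet <- match.arg(alphabet)
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "fasta") {
    seqtype <- if (alphabet == "aa") "AA" else "DNA"
    recs <- seqinr::read.fasta(path, seqtype = seqtype, as.string = FALSE,
                               forceDNAtolower = FALSE)
    if (!length(recs)) stop("no sequences in ", path)
    seqs <- lapply(recs, function(s) toupper(as.character(s)))
    names(seqs) <- names(recs)
  } else {
    seqs <- read_relaxed_phylip(path)
  }
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: row lengths ", paste(unique(lens), collapse = ", "))
  chmat <- do.call(rbind, seqs)
  alignment_from_chars(chmat, alphabet = alphabet, ref_taxon = ref_taxon)
}

# Relaxed sequential PHYLIP: header "ntaxa nchar"; each record is a name
# (any length, no whitespace) followed by its sequence, which may wrap
# over continuation lines until nchar characters are read.
read_relaxed_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  if (length(hdr) < 2L || anyNA(hdr))
    stop("malformed PHYLIP header in ", path)
  ntaxa <- hdr[1L]; nchar_exp <- hdr[2L]
  seqs <- list()
  i <- 2L
  for (k in seq_len(ntaxa)) {
    if (i > length(lines)) stop("PHYLIP file truncated: expected ", ntaxa,
                                " sequences")
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    nm <- parts[1L]
    sq <- paste(parts[-1L], collapse = "")
    i <- i + 1L
    while (nchar(sq) < nchar_exp && i <= length(lines)) {
      sq <- paste0(sq, gsub("\\s", "", lines[i]))
      i <- i + 1L
    }
    if (nchar(sq) != nchar_exp)
      stop("sequence '", nm, "' has ", nchar(sq), " characters, expected ",
           nchar_exp)
    seqs[[nm]] <- toupper(strsplit(sq, "")[[1L]])
  }
  seqs
}

# Build a phylo_alignment from a character matrix (taxa x sites for aa,
# taxa x nucleotide-sites for codon mode).
alignment_from_chars <- function(chmat, alphabet = c("aa", "codon"),
                                 ref_taxon = NULL) {
  alphabet <- match.arg(alphabet)
  taxa <- rownames(chmat)
  if (is.null(taxa)) stop("alignment rows must be named")
  if (alphabet == "aa") {
    x <- matrix(match(chmat, AA_STATES), nrow = nrow(chmat))
    states <- AA_STATES
  } else {
    if (ncol(chmat) %% 3L != 0L)
      stop("codon alignment length ", ncol(chmat), " is not divisible by 3")
    L <- ncol(chmat) %/% 3L
    cod <- matrix("", nrow(chmat), L)
    for (j in seq_len(L))
      cod[, j] <- paste0(chmat[, 3L * j - 2L], chmat[, 3L * j - 1L], chmat[, 3L * j])
    clean <- grepl("^[ACGT]{3}$", cod)
    stop_hit <- clean & matrix(cod %in% STOP_CODONS, nrow(chmat))
    if (any(stop_hit)) {
      w <- which(stop_hit, arr.ind = TRUE)[1L, ]
      stop(sprintf("in-frame stop codon '%s' in taxon '%s' at codon %d",
                   cod[w[1L], w[2L]], taxa[w[1L]], w[2L]))
    }
    x <- matrix(match(cod, CODON61), nrow(chmat))
    x[!clean] <- NA_integer_
    states <- CODON61
  }
  rownames(x) <- taxa
  if (is.null(ref_taxon)) ref_taxon <- taxa[1L]
  if (!ref_taxon %in% taxa) stop("reference taxon not in alignment: ", ref_taxon)
  structure(list(x = x, taxa = taxa, alphabet = alphabet,
                 L = ncol(x), states = states, ref_taxon = ref_taxon),
            class = "phylo_alignment")
}

# From an integer state matrix (used by the simulator).
alignment_from_states <- function(x, alphabet, ref_taxon = NULL) {
  states <- if (alphabet == "aa") AA_STATES else CODON61
  if (is.null(ref_taxon)) ref_taxon <- rownames(x)[1L]
  structure(list(x = x, taxa = rownames(x), alphabet = alphabet,
                 L = ncol(x), states = states, ref_taxon = ref_taxon),
            class = "phylo_alignment")
}

#' Translate a codon alignment to amino acids
#'
#' @param aln A codon-mode `phylo_alignment`.
#' @return An amino-acid `phylo_alignment` with the same taxa and one column
#'   per codon.
#' @export
translate_alignment <- function(aln) {
  stopifnot(inherits(aln, "phylo_alignment"))
  if (aln$alphabet != "codon") stop("translate_alignment() needs a codon alignment")
  aa <- matrix(match(CODON61_AA[aln$x], AA_STATES), nrow = nrow(aln$x))
  rownames(aa) <- aln$taxa
  alignment_from_states(aa, "aa", aln$ref_taxon)
}

#' Write an alignment to FASTA
#'
#' @param aln A `phylo_alignment`.
#' @param file Output path.
#' @export
write_alignment <- function(aln, file) {
  ch <- alignment_chars(aln)
  seqs <- lapply(seq_len(nrow(ch)), function(i) paste(ch[i, ], collapse = ""))
  seqinr::write.fasta(seqs, names = aln$taxa, file.out = file, nbchar = 60)
  invisible(file)
}

# Character representation: aa -> residues with '-' for missing; codon ->
# nucleotide triplets with '---' for missing.
alignment_chars <- function(aln) {
  if (aln$alphabet == "aa") {
    ch <- matrix(AA_STATES[aln$x], nrow = nrow(aln$x))
    ch[is.na(ch)] <- "-"
  } else {
    ch <- matrix(CODON61[aln$x], nrow = nrow(aln$x))
    ch[is.na(ch)] <- "---"
  }
  rownames(ch) <- aln$taxa
  ch
}

#' @export
print.phylo_alignment <- function(x, ...) {
  cat(sprintf("%s alignment: %d taxa x %d columns (ref taxon: %s)\n",
              if (x$alphabet == "aa") "Amino-acid" else "Codon (61-state)",
              nrow(x$x), x$L, x$ref_taxon))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * mean(is.na(x$x))))
  invisible(x)
}

# 1-based ungapped position of alignment column `col` in the reference taxon,
# NA when the reference is gapped there.
ref_positions <- function(aln) {
  r <- aln$x[aln$ref_taxon, ]
  pos <- cumsum(!is.na(r))
  pos[is.na(r)] <- NA_integer_
  pos
}
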
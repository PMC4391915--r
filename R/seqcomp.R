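# Average (isotope-abundance-weighted) residue masses, Da; a peptide bond
# has already cost each residue one water, so a chain is sum(residues) + H2O.
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0513, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

#' A protein sequence with optional functional-domain annotations
#'
#' @param id Accession or label.
#' @param sequence One-letter amino-acid string (uppercased internally).
#'   The 20 standard residues are allowed; `X` is tolerated but flagged with
#'   a warning.
#' @param species Species label.
#' @param domains Optional named list of 0-based half-open residue intervals
#'   `c(start, end)` for functional domains (e.g. `A/B`, `DBD`,
#'   `hinge/CTE`, `LBD`, `F`); must lie within the sequence and not overlap.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, species = NA_character_,
                           domains = NULL) {
  sequence <- toupper(gsub("[[:space:]*]", "", sequence))
  if (!nchar(sequence)) stop("empty protein sequence", call. = FALSE)
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(res), c(names(AA_RESIDUE_MASS), "X"))
  if (length(bad)) {
    stop("non-standard residue(s) in '", id, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if ("X" %in% res) {
    warning(sprintf("'%s' contains %d unknown (X) residue(s)", id,
                    sum(res == "X")), call. = FALSE)
  }
  if (!is.null(domains)) {
    iv <- do.call(rbind, lapply(domains, function(d) as.numeric(d[1:2])))
    if (any(iv[, 1] < 0) || any(iv[, 2] > nchar(sequence)) ||
        any(iv[, 1] >= iv[, 2])) {
      stop("domain intervals must be 0-based half-open within the sequence",
           call. = FALSE)
    }
    o <- order(iv[, 1])
    if (any(iv[o, 1][-1] < iv[o, 2][-nrow(iv)])) {
      stop("domain intervals must not overlap", call. = FALSE)
    }
  }
  structure(list(id = id, species = species, sequence = sequence,
                 domains = domains),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("protein_record %s (%s): %d aa", x$id,
              ifelse(is.na(x$species), "?", x$species), nchar(x$sequence)))
  if (!is.null(x$domains)) {
    cat(", domains:", paste(names(x$domains), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

# Longest ATG-initiated forward-strand ORF across the three frames.
# Returns NULL if none; otherwise list(start (1-based nt), nt, n_res).
find_longest_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- NULL
  chars <- strsplit(seq, "")[[1]]
  for (frame in 0:2) {
    starts <- seq.int(1 + frame, n - 2, by = 3)
    if (!length(starts)) next
    codons <- substring(seq, starts, starts + 2)
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    is_atg <- codons == "ATG"
    open_at <- NA_integer_
    for (i in seq_along(codons)) {
      if (is.na(open_at) && is_atg[i]) open_at <- i
      if (!is.na(open_at) && is_stop[i]) {
        n_res <- i - open_at
        if (n_res >= 1 && (is.null(best) || n_res > best$n_res)) {
          best <- list(start = starts[open_at],
                       nt = substr(seq, starts[open_at], starts[i] - 1),
                       n_res = n_res)
        }
        open_at <- NA_integer_
      }
    }
  }
  best
}

#' Find and translate the longest open reading frame
#'
#' Scans the forward strand in all three frames for the longest
#' ATG-initiated ORF ending at an in-frame stop, and translates it with the
#' standard genetic code (stop excluded). With `both_strands = TRUE` the
#' reverse complement is scanned too.
#'
#' @param nucleotides DNA string over `A`, `C`, `G`, `T`, `N` (length >= 6).
#' @param id,species Labels for the resulting record.
#' @param both_strands Also scan the reverse complement.
#' @return A [protein_record()].
#' @examples
#' longest_orf_translate("ATGAAATAA")$sequence  # "MK"
#' @export
longest_orf_translate <- function(nucleotides, id = "orf",
                                  species = NA_character_,
                                  both_strands = FALSE) {
  seq <- toupper(gsub("[[:space:]]", "", nucleotides))
  if (nchar(seq) < 6) stop("sequence must be >= 6 nt", call. = FALSE)
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop("sequence contains non-ACGTN characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  best <- find_longest_orf(seq)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    alt <- find_longest_orf(rc)
    if (!is.null(alt) && (is.null(best) || alt$n_res > best$n_res)) best <- alt
  }
  if (is.null(best)) {
    stop("no ATG-initiated ORF with an in-frame stop found", call. = FALSE)
  }
  if (grepl("N", best$nt, fixed = TRUE)) {
    stop("ambiguous base (N) within the longest ORF", call. = FALSE)
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(best$nt)))
  protein_record(id = id, sequence = aa, species = species)
}

#' Protein molecular weight from average residue masses
#'
#' Sum of isotope-abundance-weighted average residue masses plus one water,
#' reported in kilodaltons.
#'
#' @param protein A [protein_record()] or plain amino-acid string.
#' @return Mass in kDa (numeric; print with 1 decimal to match convention).
#' @examples
#' molecular_weight("G")  # 0.0750666 kDa
#' @export
molecular_weight <- function(protein) {
  seq <- if (inherits(protein, "protein_record")) protein$sequence
         else toupper(protein)
  res <- strsplit(seq, "")[[1]]
  bad <- which(!res %in% names(AA_RESIDUE_MASS))
  if (length(bad)) {
    stop("non-standard residue(s) at position(s): ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)
  }
  (sum(AA_RESIDUE_MASS[res]) + WATER_MASS) / 1000
}

region_sequence <- function(rec, domain) {
  if (is.null(domain)) return(rec$sequence)
  if (is.null(rec$domains) || !domain %in% names(rec$domains)) {
    stop(sprintf("record '%s' lacks a '%s' domain annotation", rec$id,
                 domain), call. = FALSE)
  }
  iv <- rec$domains[[domain]]
  out <- substr(rec$sequence, iv[1] + 1, iv[2])  # 0-based half-open
  if (!nchar(out)) stop("empty domain region", call. = FALSE)
  out
}

#' Pairwise percent identity by global alignment
#'
#' Needleman-Wunsch global alignment of the two (optionally domain-restricted)
#' sequences under BLOSUM62 with affine gap penalties (open 10, extend 0.5).
#' Identity is the number of identical aligned residue pairs divided by the
#' number of alignment columns in which **both** sequences have a residue
#' (`denominator = "aligned"`), or by all alignment columns including gaps
#' (`denominator = "columns"`), times 100.
#'
#' @param a,b [protein_record()]s (or plain strings).
#' @param domain Optional domain name; both records must carry it.
#' @param denominator `"aligned"` (gap-excluded, default) or `"columns"`.
#' @return Percent identity in \[0, 100\].
#' @export
percent_identity <- function(a, b, domain = NULL,
                             denominator = c("aligned", "columns")) {
  denominator <- match.arg(denominator)
  if (!inherits(a, "protein_record")) a <- protein_record("a", a)
  if (!inherits(b, "protein_record")) b <- protein_record("b", b)
  sa <- region_sequence(a, domain)
  sb <- region_sequence(b, domain)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  both <- pa != "-" & pb != "-"
  denom <- if (denominator == "aligned") sum(both) else length(pa)
  if (denom == 0) stop("alignment has no residue-residue columns",
                       call. = FALSE)
  100 * sum(pa[both] == pb[both]) / denom
}

#' All-pairs percent-identity table
#'
#' Symmetric matrix of pairwise global-alignment identities across records,
#' with 100 on the diagonal — the layout of a full-length or per-domain
#' receptor homology table.
#'
#' @param records List of [protein_record()]s (>= 2, unique ids).
#' @param domain Optional domain name restricting the comparison.
#' @param ... Passed to [percent_identity()].
#' @return An object of class `identity_table`: the numeric matrix with a
#'   `labels` attribute.
#' @export
identity_table <- function(records, domain = NULL, ...) {
  if (length(records) < 2) stop("need >= 2 records", call. = FALSE)
  labs <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(labs)) stop("record ids must be unique", call. = FALSE)
  n <- length(records)
  m <- diag(100, n)
  dimnames(m) <- list(labs, labs)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      pid <- tryCatch(
        percent_identity(records[[i]], records[[j]], domain = domain, ...),
        error = function(e) stop(sprintf("pair (%s, %s): %s", labs[i],
                                         labs[j], conditionMessage(e)),
                                 call. = FALSE))
      m[i, j] <- pid
      m[j, i] <- pid
    }
  }
  structure(m, class = c("identity_table", "matrix"))
}

#' @export
print.identity_table <- function(x, digits = 0, ...) {
  cat("Percent-identity table:\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Write an identity table as TSV
#'
#' @param x An [identity_table()].
#' @param file Path to write.
#' @return The path, invisibly.
#' @export
write_identity_table <- function(x, file) {
  df <- data.frame(id = rownames(x), unclass(x), check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read protein sequences from FASTA into protein records
#'
#' @param file FASTA path.
#' @param domains Optional named list (by record id) of domain maps as in
#'   [protein_record()].
#' @return List of [protein_record()]s.
#' @export
read_protein_fasta <- function(file, domains = NULL) {
  aa <- Biostrings::readAAStringSet(file)
  ids <- sub("\\s.*$", "", names(aa))
  lapply(seq_along(aa), function(i) {
    protein_record(ids[i], as.character(aa[[i]]),
                   domains = domains[[ids[i]]])
  })
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences (protein or DNA), or a
#'   list of [protein_record()]s.
#' @param file Path to write.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, file) {
  if (is.list(seqs) && all(vapply(seqs, inherits, logical(1),
                                  "protein_record"))) {
    seqs <- setNames(vapply(seqs, function(r) r$sequence, character(1)),
                     vapply(seqs, function(r) r$id, character(1)))
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, file)
  invisible(file)
}
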
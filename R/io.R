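# Readers and writers for the standard formats the toolkit touches.
#
# Conventions: internal coordinates are 1-based closed (the Biostrings/IRanges
# convention); conversion to 0-based half-open happens only in the BED-like
# writer, and VCF/GFF are 1-based by definition. All TSV outputs carry a
# commented '#' header line.

#' Construct a genome set
#'
#' A genome set is one accession's assembly: an ordered, named collection of
#' chromosome sequences over {A,C,G,T,N}.
#'
#' @param accession accession label
#' @param sequences named character vector of chromosome sequences
#' @return object of class \code{genome_set}
#' @export
genome_set <- function(accession, sequences) {
  if (is.null(names(sequences)) || anyNA(names(sequences)) || any(names(sequences) == ""))
    .stopf("all chromosome sequences must be named")
  if (anyDuplicated(names(sequences)))
    .stopf("duplicate chromosome name in accession '%s': %s", accession,
           names(sequences)[duplicated(names(sequences))][1L])
  if (any(nchar(sequences) == 0L))
    .stopf("empty chromosome sequence in accession '%s'", accession)
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) sequences[bad] <- gsub("[^ACGTN]", "N", sequences[bad])
  structure(list(accession = accession, sequences = sequences),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set:", x$accession, "-", length(x$sequences), "chromosome(s),",
      format(sum(nchar(x$sequences)), big.mark = ","), "nt total\n")
  invisible(x)
}

#' Read a genome assembly from FASTA
#'
#' One chromosome per record, record order preserved. Lowercase is normalised
#' to uppercase and any symbol outside {A,C,G,T,N} is mapped to N.
#'
#' @param path FASTA file
#' @param accession accession label; defaults to the file name without extension
#' @return a \code{genome_set}
#' @export
read_fasta <- function(path, accession = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) .stopf("empty FASTA file: %s", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    .stopf("duplicate FASTA record name: %s", nm[duplicated(nm)][1L])
  seqs <- as.character(ss)
  names(seqs) <- nm
  accession <- accession %||% sub("\\.[^.]*$", "", basename(path))
  genome_set(accession, seqs)
}

#' Write a genome set to FASTA
#'
#' @param genome a \code{genome_set}
#' @param path output file
#' @return invisibly, the path
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Construct a TE annotation set
#'
#' @param elements data.frame with columns element_id, superfamily, sequence
#' @return object of class \code{te_annotation_set}
#' @export
te_annotation_set <- function(elements) {
  need <- c("element_id", "superfamily", "sequence")
  if (!all(need %in% names(elements))) .stopf("elements must have columns %s",
                                              paste(need, collapse = ", "))
  if (anyDuplicated(elements$element_id))
    .stopf("duplicate element_id: %s",
           elements$element_id[duplicated(elements$element_id)][1L])
  elements$sequence <- toupper(elements$sequence)
  structure(list(elements = elements), class = "te_annotation_set")
}

#' @export
print.te_annotation_set <- function(x, ...) {
  cat("te_annotation_set:", nrow(x$elements), "element(s),",
      length(unique(x$elements$superfamily)), "superfamilies\n")
  invisible(x)
}

#' Read a TE annotation (FASTA library or GFF3 intervals)
#'
#' A FASTA file is read as a library of consensus element sequences (the
#' superfamily label is taken from the second whitespace-separated token of
#' the header, if any). A GFF3 file requires \code{genome}; element sequences
#' are extracted from the annotated intervals, reverse-complemented for
#' minus-strand features.
#'
#' @param path FASTA library or GFF3 file
#' @param genome \code{genome_set} the GFF3 intervals refer to, or NULL
#' @return a \code{te_annotation_set}
#' @export
read_te_annotation <- function(path, genome = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  first <- readLines(path, n = 50L)
  first <- first[nzchar(first)]
  if (length(first) == 0L) .stopf("empty annotation file: %s", path)
  if (startsWith(first[1L], ">")) {
    ss <- Biostrings::readBStringSet(path)
    nm <- names(ss)
    ids <- sub("\\s.*$", "", nm)
    fam <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "unknown")
    fam <- sub("\\s.*$", "", fam)
    return(te_annotation_set(data.frame(
      element_id = ids, superfamily = fam,
      sequence = gsub("[^ACGTN]", "N", toupper(as.character(ss))),
      stringsAsFactors = FALSE)))
  }
  if (is.null(genome))
    .stopf("GFF3 annotation requires a genome to extract element sequences from")
  gff <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(gff) < 9L) .stopf("malformed GFF3: expected 9 columns")
  names(gff) <- c("seqid", "source", "type", "start", "end", "score",
                  "strand", "phase", "attributes")
  attr_field <- function(a, key) {
    m <- regmatches(a, regexpr(paste0("(^|;)\\s*", key, "=[^;]+"), a))
    ifelse(lengths(regmatches(a, gregexpr(paste0("(^|;)\\s*", key, "=[^;]+"), a))) > 0,
           sub(paste0("^.*", key, "="), "", m), NA_character_)
  }
  ids <- vapply(seq_len(nrow(gff)), function(i) {
    a <- gff$attributes[i]
    id <- sub(".*(^|;)ID=([^;]+).*", "\\2", a)
    if (identical(id, a)) id <- sub(".*(^|;)Name=([^;]+).*", "\\2", a)
    if (identical(id, a)) id <- sprintf("te_%d", i)
    id
  }, character(1))
  fam <- vapply(seq_len(nrow(gff)), function(i) {
    a <- gff$attributes[i]
    f <- sub(".*(^|;)superfamily=([^;]+).*", "\\2", a)
    if (identical(f, a)) f <- gff$type[i]
    f
  }, character(1))
  seqs <- character(nrow(gff))
  for (i in seq_len(nrow(gff))) {
    chrom <- gff$seqid[i]
    if (!chrom %in% names(genome$sequences))
      .stopf("GFF3 feature '%s': unknown chromosome '%s'", ids[i], chrom)
    L <- nchar(genome$sequences[[chrom]])
    if (gff$start[i] < 1L || gff$end[i] > L || gff$start[i] > gff$end[i])
      .stopf("GFF3 feature '%s' is out of bounds on '%s' (1..%d)", ids[i], chrom, L)
    s <- substring(genome$sequences[[chrom]], gff$start[i], gff$end[i])
    if (gff$strand[i] == "-") s <- revcomp(s)
    seqs[i] <- s
  }
  te_annotation_set(data.frame(element_id = ids, superfamily = fam,
                               sequence = seqs, stringsAsFactors = FALSE))
}

# ---- writers -----------------------------------------------------------

#' Write SNP calls as VCF v4.2
#'
#' Haploid genotypes (the accessions are inbred lines). POS is the 1-based
#' position in the anchor accession (the alignment's first accession), and
#' the pangenome column is carried in the INFO field.
#'
#' @param snps \code{snp_set} from \code{\link{call_snps}}
#' @param path output file
#' @param contig_lengths named vector of anchor-accession chromosome lengths
#'   (optional; written as contig header lines when given)
#' @return invisibly, the path
#' @export
write_snps_vcf <- function(snps, path, contig_lengths = NULL) {
  acc <- attr(snps, "accessions")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=panwga",
           "##INFO=<ID=PC,Number=1,Type=Integer,Description=\"Pangenome column\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">")
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                          as.integer(contig_lengths)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", acc), collapse = "\t"))
  if (nrow(snps) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  bases <- snps$alleles  # n-character strings, one base per accession
  n <- nchar(bases[1L])
  bm <- do.call(rbind, strsplit(bases, ""))
  ref <- bm[, 1L]
  alt <- vapply(seq_len(nrow(bm)), function(i) {
    a <- setdiff(unique(bm[i, ]), ref[i])
    paste(a, collapse = ",")
  }, character(1))
  gt <- vapply(seq_len(nrow(bm)), function(i) {
    lv <- c(ref[i], strsplit(alt[i], ",")[[1L]])
    paste(match(bm[i, ], lv) - 1L, collapse = "\t")
  }, character(1))
  body <- paste(snps$anchor_chrom, snps$anchor_pos, ".", ref, alt, ".", "PASS",
                sprintf("PC=%d", snps$col), "GT", gt, sep = "\t")
  o <- order(snps$anchor_chrom, snps$anchor_pos)
  writeLines(c(hdr, body[o]), path)
  invisible(path)
}

#' Read a SNP call set from VCF or a 3+-column TSV
#'
#' Accepts the VCF written by \code{\link{write_snps_vcf}} (or any VCF with
#' single-base REF/ALT) or a TSV with columns chrom, pos, alleles. Used by the
#' concordance module to ingest external call sets.
#'
#' @param path input file
#' @return data.frame with columns chrom, pos, ref, alt, het (logical; TRUE
#'   when any genotype in the record is heterozygous)
#' @export
read_call_set <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  if (any(startsWith(lines, "##fileformat=VCF"))) {
    body <- lines[!startsWith(lines, "#")]
    if (length(body) == 0L)
      return(data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0), het = logical(0)))
    f <- strsplit(body, "\t", fixed = TRUE)
    chrom <- vapply(f, `[`, "", 1L)
    pos <- as.integer(vapply(f, `[`, "", 2L))
    ref <- vapply(f, `[`, "", 4L)
    alt <- vapply(f, `[`, "", 5L)
    het <- vapply(f, function(x) {
      if (length(x) < 10L) return(FALSE)
      any(grepl("^([0-9]+)[/|]([0-9]+)", x[10:length(x)]) &
            !grepl("^([0-9]+)[/|]\\1(:|$)", x[10:length(x)]))
    }, logical(1))
    return(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, het = het,
                      stringsAsFactors = FALSE))
  }
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  data.frame(chrom = as.character(tab[[1L]]), pos = as.integer(tab[[2L]]),
             ref = substr(as.character(tab[[3L]]), 1L, 1L),
             alt = substr(as.character(tab[[3L]]), nchar(as.character(tab[[3L]])),
                          nchar(as.character(tab[[3L]]))),
             het = FALSE, stringsAsFactors = FALSE)
}

#' Write SV loci as a BED-like TSV plus allele FASTA
#'
#' Pangenome coordinates are emitted 0-based half-open; per-accession allele
#' lengths follow in accession order. Allele (presence) sequences go to a
#' companion FASTA when \code{fasta} is given.
#'
#' @param svs \code{sv_set}
#' @param path TSV output
#' @param fasta optional FASTA output of per-locus consensus presence alleles
#' @return invisibly, the path
#' @export
write_svs_tsv <- function(svs, path, fasta = NULL) {
  acc <- attr(svs, "accessions")
  hdr <- paste0("#chrom\tstart\tend\tsv_id\tlength\tclass\tpresence_freq\tpolarity\tterminal\t",
                paste0("len_", acc, collapse = "\t"))
  lens <- attr(svs, "allele_lengths")
  rows <- character(nrow(svs))
  for (i in seq_len(nrow(svs))) {
    rows[i] <- paste(c(svs$chrom[i], svs$col_start[i] - 1L, svs$col_end[i],
                       svs$sv_id[i], svs$L[i],
                       svs$class[i] %||% NA, round(svs$presence_freq[i], 4),
                       svs$polarity[i] %||% NA, svs$terminal[i],
                       lens[i, ]), collapse = "\t")
  }
  writeLines(c(hdr, rows), path)
  if (!is.null(fasta)) {
    seqs <- attr(svs, "consensus")
    if (is.null(seqs)) {
      seqs <- vapply(seq_len(nrow(svs)), function(i)
        consensus_allele(svs, i), character(1))
    }
    keep <- nchar(seqs) > 0L
    ss <- Biostrings::DNAStringSet(seqs[keep])
    names(ss) <- svs$sv_id[keep]
    Biostrings::writeXStringSet(ss, filepath = fasta)
  }
  invisible(path)
}

#' Write a nestedness graph as edge-list and node TSVs
#'
#' @param graph \code{nestedness_graph}
#' @param edge_path edge-list TSV (nested_id, container_id, coverage)
#' @param node_path optional node table TSV
#' @return invisibly, \code{edge_path}
#' @export
write_graph_tsv <- function(graph, edge_path, node_path = NULL) {
  e <- graph$edges
  writeLines(c("#nested_id\tcontainer_id\tcoverage",
               if (nrow(e)) paste(e$nested_id, e$container_id,
                                  round(e$coverage, 4), sep = "\t")),
             edge_path)
  if (!is.null(node_path)) {
    nd <- graph$nodes
    writeLines(c("#node_id\tlength\tte_category\tmembers\tcomponent",
                 if (nrow(nd)) paste(nd$node_id, nd$length, nd$te_category,
                                     nd$members, nd$component, sep = "\t")),
               node_path)
  }
  invisible(edge_path)
}

#' Write a generic table as a commented-header TSV
#'
#' @param df data.frame
#' @param path output file
#' @return invisibly, the path
#' @export
write_table_tsv <- function(df, path) {
  hdr <- paste0("#", paste(names(df), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a commented-header TSV written by \code{write_table_tsv}
#'
#' @param path input file
#' @return data.frame
#' @export
read_table_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  cols <- strsplit(sub("^#", "", hdr), "\t", fixed = TRUE)[[1L]]
  out <- utils::read.delim(path, header = FALSE, skip = 1L,
                           col.names = cols, stringsAsFactors = FALSE)
  if (nrow(out) == 0L) out <- out[, cols, drop = FALSE]
  out
}

#' Write all downstream results to a directory
#'
#' Dispatches on the components present in \code{results}: \code{snps} (VCF),
#' \code{svs} (TSV + allele FASTA), \code{graph} (edge/node TSVs),
#' \code{saturation}, \code{taxonomy}, \code{inversions} (TSVs).
#'
#' @param results named list of results
#' @param out_dir output directory (created if needed)
#' @return invisibly, a character vector of files written
#' @export
write_outputs <- function(results, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2L) != 0L)
    .stopf("cannot write to directory: %s", out_dir)
  written <- character(0)
  fp <- function(f) file.path(out_dir, f)
  if (!is.null(results$snps)) {
    write_snps_vcf(results$snps, fp("snps.vcf"))
    written <- c(written, fp("snps.vcf"))
  }
  if (!is.null(results$svs)) {
    write_svs_tsv(results$svs, fp("sv_loci.tsv"), fasta = fp("sv_alleles.fasta"))
    written <- c(written, fp("sv_loci.tsv"), fp("sv_alleles.fasta"))
  }
  if (!is.null(results$graph)) {
    write_graph_tsv(results$graph, fp("nestedness_edges.tsv"), fp("nestedness_nodes.tsv"))
    written <- c(written, fp("nestedness_edges.tsv"), fp("nestedness_nodes.tsv"))
  }
  for (nm in c("saturation", "taxonomy", "inversions", "dilation")) {
    if (!is.null(results[[nm]])) {
      write_table_tsv(as.data.frame(results[[nm]]), fp(paste0(nm, ".tsv")))
      written <- c(written, fp(paste0(nm, ".tsv")))
    }
  }
  invisible(written)
}
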
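#' Parse a functionally annotated VCF into variant records
#'
#' Reads a VCF 4.x file whose INFO column carries VEP-style consequence
#' annotation (one `|`-separated annotation string per transcript/allele, the
#' subfield layout declared in the `##INFO=<ID=CSQ,...Format=...>` header
#' line). One record is emitted per (site, alt allele, annotated gene) triple;
#' multi-allelic sites are expanded. When the annotation format has an
#' `Allele` subfield it is matched against the alt allele string; otherwise
#' each annotation applies to every alt allele of the site.
#'
#' @param path path to an (uncompressed or bgzipped) VCF file.
#' @param csq_field INFO field holding the annotation (default `"CSQ"`).
#' @param gene_subfield annotation subfield with the gene symbol (default
#'   `"SYMBOL"`).
#' @param consequence_subfield annotation subfield with the consequence terms
#'   (default `"Consequence"`).
#' @return An object of class `variant_records`: a data.frame with columns
#'   `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`, and an attribute
#'   `"dosage"` — an integer matrix (records x samples) of alt-allele counts
#'   per genotype (`NA` for missing genotypes).
#' @export
parse_annotated_vcf <- function(path, csq_field = "CSQ",
                                gene_subfield = "SYMBOL",
                                consequence_subfield = "Consequence") {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  hdr <- VariantAnnotation::scanVcfHeader(path)
  info_df <- VariantAnnotation::info(hdr)
  if (!csq_field %in% rownames(info_df)) {
    stop(sprintf("INFO field '%s' not declared in the VCF header of %s",
                 csq_field, path), call. = FALSE)
  }
  desc <- info_df[csq_field, "Description"]
  fmt <- sub(".*Format:\\s*", "", desc)
  fmt_fields <- trimws(strsplit(fmt, "|", fixed = TRUE)[[1]])
  for (f in c(gene_subfield, consequence_subfield)) {
    if (!f %in% fmt_fields) {
      stop(sprintf("annotation subfield '%s' not in declared Format (%s)",
                   f, paste(fmt_fields, collapse = "|")), call. = FALSE)
    }
  }
  vcf <- VariantAnnotation::readVcf(path)
  samples <- colnames(vcf)
  nrec <- nrow(vcf)
  empty <- function() {
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), gene = character(),
                      consequence = character(), stringsAsFactors = FALSE)
    attr(out, "dosage") <- matrix(integer(), nrow = 0L, ncol = length(samples),
                                  dimnames = list(NULL, samples))
    class(out) <- c("variant_records", "data.frame")
    out
  }
  if (nrec == 0L) return(empty())

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(rr$REF)
  alt_list <- lapply(VariantAnnotation::alt(vcf), as.character)
  csq_list <- as.list(VariantAnnotation::info(vcf)[[csq_field]])
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT genotype field: ", path, call. = FALSE)

  gi <- match(gene_subfield, fmt_fields)
  ci <- match(consequence_subfield, fmt_fields)
  ai <- match("Allele", fmt_fields)

  rows <- vector("list", nrec)
  dosages <- vector("list", nrec)
  for (r in seq_len(nrec)) {
    alts <- alt_list[[r]]
    anns <- csq_list[[r]]
    if (length(anns) == 0L || all(is.na(anns))) next
    parsed <- strsplit(anns, "|", fixed = TRUE)
    badlen <- vapply(parsed, length, 1L) != length(fmt_fields)
    if (any(badlen)) {
      stop(sprintf("annotation at %s:%d has %d subfields, header declares %d",
                   chrom[r], pos[r], length(parsed[[which(badlen)[1]]]),
                   length(fmt_fields)), call. = FALSE)
    }
    # alt-allele dosage per sample, one row per alt index
    dos <- t(vapply(seq_along(alts), function(k) {
      alleles <- strsplit(gt[r, ], "[/|]")
      vapply(alleles, function(al) {
        if (any(al %in% c(".", ""))) return(NA_integer_)
        sum(al == as.character(k))
      }, integer(1L))
    }, integer(length(samples))))
    if (length(samples) == 1L) dos <- matrix(dos, ncol = 1L)
    for (p in parsed) {
      gene <- trimws(p[gi])
      if (!nzchar(gene)) next
      csq <- p[ci]
      if (!is.na(ai)) {
        k <- match(p[ai], alts)
        if (is.na(k)) next  # annotation for an allele not present (e.g. ref)
        kk <- k
      } else {
        kk <- seq_along(alts)
      }
      for (k in kk) {
        rows[[r]] <- c(rows[[r]], list(data.frame(
          chrom = chrom[r], pos = pos[r], ref = ref[r], alt = alts[k],
          gene = gene, consequence = csq, stringsAsFactors = FALSE)))
        dosages[[r]] <- c(dosages[[r]], list(dos[k, ]))
      }
    }
  }
  rows <- unlist(rows, recursive = FALSE)
  dosages <- unlist(dosages, recursive = FALSE)
  if (length(rows) == 0L) return(empty())
  out <- do.call(rbind, rows)
  dmat <- do.call(rbind, dosages)
  colnames(dmat) <- samples
  attr(out, "dosage") <- dmat
  class(out) <- c("variant_records", "data.frame")
  out
}

#' Keep only missense variants
#'
#' Consequence strings are split on `&` (VEP compound terms such as
#' `missense_variant&splice_region_variant`) and kept when any term equals
#' `missense_variant`.
#'
#' @param records a `variant_records` object from [parse_annotated_vcf()].
#' @param term consequence term to select (default `"missense_variant"`).
#' @return A filtered `variant_records` object.
#' @export
filter_missense <- function(records, term = "missense_variant") {
  keep <- vapply(strsplit(records$consequence, "&", fixed = TRUE),
                 function(x) term %in% trimws(x), logical(1L))
  subset_records(records, keep)
}

subset_records <- function(records, keep) {
  dos <- attr(records, "dosage")
  out <- as.data.frame(records)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dosage") <- dos[keep, , drop = FALSE]
  class(out) <- c("variant_records", "data.frame")
  out
}

#' Per-gene missense burden counts
#'
#' Builds the gene x sample count matrix used as node attributes. In `"site"`
#' mode an entry is the number of distinct variant records in the gene where
#' the sample carries at least one alt allele; in `"dosage"` mode it is the
#' sum of alt-allele counts (so a homozygote contributes 2 per site). Missing
#' genotypes contribute 0. Genes with no records get a zero row; records for
#' genes outside `genes` are ignored.
#'
#' @param records a `variant_records` object.
#' @param genes ordered character vector of genes (matrix row order).
#' @param samples ordered character vector of sample ids (column order);
#'   defaults to the samples in `records`.
#' @param mode `"site"` (default) or `"dosage"`.
#' @return An integer matrix (genes x samples) of class `count_matrix`.
#' @export
count_per_gene <- function(records, genes, samples = NULL,
                           mode = c("site", "dosage")) {
  mode <- match.arg(mode)
  dos <- attr(records, "dosage")
  if (is.null(samples)) samples <- colnames(dos)
  if (anyDuplicated(samples)) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(genes)) stop("duplicate gene symbols", call. = FALSE)
  m <- matrix(0L, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  if (nrow(records) > 0L) {
    missing_s <- setdiff(samples, colnames(dos))
    if (length(missing_s)) {
      stop("sample(s) not present in the VCF: ", paste(missing_s, collapse = ", "),
           call. = FALSE)
    }
    d <- dos[, samples, drop = FALSE]
    d[is.na(d)] <- 0L
    contrib <- if (mode == "site") (d > 0L) * 1L else d
    for (i in which(records$gene %in% genes)) {
      g <- records$gene[i]
      m[g, ] <- m[g, ] + contrib[i, ]
    }
  }
  count_matrix(m)
}

#' Count matrix constructor / validator
#'
#' A `count_matrix` is a plain integer matrix (genes x samples) with unique
#' dimnames and non-negative entries.
#'
#' @param m numeric matrix with gene rownames and sample colnames.
#' @return The validated integer matrix with class `count_matrix`.
#' @export
count_matrix <- function(m) {
  stopifnot(is.matrix(m))
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("count matrix needs gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids", call. = FALSE)
  if (any(is.na(m))) stop("count matrix contains NA", call. = FALSE)
  if (any(m < 0)) stop("count matrix contains negative entries", call. = FALSE)
  if (any(m != round(m))) stop("count matrix contains non-integer entries", call. = FALSE)
  storage.mode(m) <- "integer"
  class(m) <- c("count_matrix", class(matrix()))
  m
}

#' Read / write a gene x sample count table
#'
#' TSV layout: header row of sample ids (first column name `gene`), one row
#' per gene. Ragged rows, negative or non-integer entries are rejected.
#'
#' @param path file path.
#' @return `load_count_table()`: a [count_matrix()]; `write_count_table()`:
#'   `path`, invisibly.
#' @export
load_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#")
  if (length(unique(nf)) > 1L) {
    stop(sprintf("ragged count table %s: rows have %s fields", path,
                 paste(unique(nf), collapse = "/")), call. = FALSE)
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("count table has non-numeric entries", call. = FALSE)
  rownames(m) <- genes
  count_matrix(m)
}

#' @param counts a [count_matrix()].
#' @rdname load_count_table
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
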
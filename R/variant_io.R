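#' Read a VCF file into a variant table and genotype matrix
#'
#' Parses a VCF v4.x file (via vcfR), keeping 1-based positions, mapping
#' missing genotypes (`./.` or any partially missing call) to `NA`, and
#' splitting multi-allelic sites into one biallelic record per alternate
#' allele (the dosage counts copies of that specific allele). `GENE=` and
#' `REGION=` INFO keys and `##SAMPLE=<ID=...,Status=case|control>` header
#' lines written by [write_vcf()] are recovered when present.
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @return a `cohort` object (truth/config empty) with `variants`,
#'   `genotypes` and (if encoded) `phenotype`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("no such file: ", path))
  header <- character()
  con <- file(path, "r")
  on.exit(close(con), add = TRUE)
  lineno <- 0L
  repeat {
    ln <- readLines(con, n = 1L)
    lineno <- lineno + 1L
    if (!length(ln)) {
      stop_validation(sprintf("malformed VCF header: no #CHROM line by line %d",
                              lineno))
    }
    if (startsWith(ln, "##")) { header <- c(header, ln); next }
    if (startsWith(ln, "#CHROM")) break
    stop_validation(sprintf("malformed VCF header at line %d: %s", lineno,
                            substr(ln, 1, 40)))
  }
  if (!any(grepl("^##fileformat=VCFv4", header))) {
    stop_validation("malformed VCF header at line 1: missing ##fileformat=VCFv4.x")
  }

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) > 0) {
    fmt <- vcf@gt[, "FORMAT"]
    if (is.null(fmt) || !all(vapply(strsplit(fmt, ":"), function(f)
      "GT" %in% f, logical(1)))) {
      stop_validation("VCF records lack a GT FORMAT field")
    }
  }

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt_raw)

  info_field <- function(info, key) {
    v <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    v
  }

  rows <- list(); gts <- list()
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
    tokens <- strsplit(gt_raw[r, ], "[/|]")
    for (k in seq_along(alts)) {
      dos <- vapply(tokens, function(tk) {
        if (length(tk) == 0 || anyNA(tk) || any(tk == ".")) return(NA_integer_)
        sum(tk == as.character(k))
      }, integer(1))
      rows[[length(rows) + 1L]] <- tibble(
        chrom = fix$CHROM[r],
        pos = as.integer(fix$POS[r]),
        id = ifelse(is.na(fix$ID[r]) | fix$ID[r] == ".", NA_character_,
                    fix$ID[r]),
        ref = fix$REF[r],
        alt = alts[k],
        gene = info_field(fix$INFO[r], "GENE"),
        region_class = info_field(fix$INFO[r], "REGION")
      )
      gts[[length(gts) + 1L]] <- dos
    }
  }
  variants <- bind_rows(rows)
  variants <- mutate(variants,
                     variant = variant_key(.data$chrom, .data$pos, .data$ref,
                                           .data$alt),
                     .before = 1)
  G <- do.call(rbind, gts)
  if (is.null(G)) G <- matrix(integer(), 0, length(samples))
  dimnames(G) <- list(variants$variant, samples)

  phenotype <- NULL
  samp_lines <- grep("^##SAMPLE=<", header, value = TRUE)
  if (length(samp_lines)) {
    ids <- stringr::str_match(samp_lines, "ID=([^,>]+)")[, 2]
    status <- stringr::str_match(samp_lines, "Status=([^,>]+)")[, 2]
    phenotype <- setNames(as.integer(status == "case"), ids)[samples]
    names(phenotype) <- samples
  }
  structure(list(variants = variants, genotypes = G, phenotype = phenotype,
                 truth = NULL, config = NULL),
            class = "cohort")
}

#' Write a variant table and genotype matrix as VCF v4.2
#'
#' Records are emitted in deterministic (chromosome, position, alt) order
#' with `GENE=`/`REGION=` INFO keys; phenotypes, when given, are encoded as
#' `##SAMPLE` header lines so [read_vcf()] round-trips the full object. The
#' header carries no timestamp, so two writes of the same data are
#' byte-identical.
#'
#' @param variants variant tibble (`chrom`, `pos`, `id`, `ref`, `alt`,
#'   optionally `gene`, `region_class`).
#' @param genotypes variants x individuals dosage matrix (0/1/2/NA), rows in
#'   the order of `variants`.
#' @param path output path.
#' @param phenotype optional named binary vector over the matrix columns.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes, path, phenotype = NULL) {
  if (nrow(variants) != nrow(genotypes)) {
    stop_validation(sprintf(
      "variant table (%d rows) and genotype matrix (%d rows) are inconsistent",
      nrow(variants), nrow(genotypes)))
  }
  samples <- colnames(genotypes)
  if (is.null(samples)) samples <- sprintf("S%04d", seq_len(ncol(genotypes)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=centiskat",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=REGION,Number=1,Type=String,Description=\"Genomic region class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  if (!is.null(phenotype)) {
    header <- c(header, sprintf(
      "##SAMPLE=<ID=%s,Status=%s>", samples,
      ifelse(phenotype[samples] == 1L, "case", "control")))
  }
  ord <- order(variants$chrom, variants$pos, variants$alt)
  v <- variants[ord, ]
  G <- genotypes[ord, , drop = FALSE]

  parts <- cbind(
    if ("gene" %in% names(v)) ifelse(is.na(v$gene), NA,
                                     paste0("GENE=", v$gene)) else NA,
    if ("region_class" %in% names(v)) ifelse(is.na(v$region_class), NA,
                                             paste0("REGION=", v$region_class))
    else NA
  )
  info <- apply(parts, 1, function(p) {
    p <- p[!is.na(p)]
    if (length(p)) paste(p, collapse = ";") else "."
  })

  gt_chr <- matrix(c("0/0", "0/1", "1/1")[G + 1L], nrow = nrow(G))
  gt_chr[is.na(G)] <- "./."

  body <- paste(
    v$chrom, v$pos, ifelse(is.na(v$id), ".", v$id), v$ref, v$alt, ".", "PASS",
    info, "GT",
    apply(gt_chr, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  if (nrow(v) == 0) body <- character()
  col_line <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t")
  writeLines(c(header, col_line, body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a typed tab-separated table
#'
#' Schema-validated readers for the pipeline's tabular formats. Unknown
#' columns are preserved as passthrough; schema violations are rejected
#' rather than coerced.
#'
#' @param path file path. `gene_sets` expects GMT (set name, description,
#'   then member genes, tab-separated); everything else is TSV with a header.
#' @param schema one of `"pool_af"`, `"annotations"`, `"gene_sets"`,
#'   `"edges"`, `"results"`.
#' @return for `pool_af` a `pool_af` object; for `gene_sets` a named list of
#'   character vectors; otherwise a tibble.
#' @export
read_table <- function(path, schema = c("pool_af", "annotations", "gene_sets",
                                        "edges", "results")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop_validation(paste0("no such file: ", path))

  require_cols <- function(df, cols) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop_validation(paste0("missing required column(s): ",
                             paste(miss, collapse = ", ")))
    }
  }

  if (schema == "gene_sets") {
    sets <- fgsea::gmtPathways(path)
    if (!length(sets)) stop_validation("empty gene-set file")
    sets <- lapply(sets, function(g) {
      g <- g[g != ""]
      unique(g)
    })
    empty <- vapply(sets, length, integer(1)) == 0
    if (any(empty)) {
      stop_validation(paste0("empty gene set(s): ",
                             paste(names(sets)[empty], collapse = ", ")))
    }
    return(sets)
  }

  if (schema == "edges") {
    first <- readLines(path, n = 1L)
    has_header <- identical(tolower(strsplit(first, "\t")[[1]])[1:2],
                            c("from", "to"))
    df <- readr::read_tsv(path, col_names = has_header,
                          show_col_types = FALSE)
    if (!has_header) names(df)[1:2] <- c("from", "to")
    names(df)[1:2] <- c("from", "to")
    if (ncol(df) < 2) stop_validation("edge list needs two columns")
    return(as_tibble(df))
  }

  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)

  if (schema == "pool_af") {
    require_cols(df, c("variant", "pool", "af", "phenotype", "size", "depth"))
    bad <- which(df$af < 0 | df$af > 1)
    if (length(bad)) {
      stop_validation(sprintf("allele frequency outside [0,1] at row %d",
                              bad[1]), row = bad[1])
    }
    if (any(df$size < 1)) stop_validation("pool size must be >= 1")
    af_wide <- tidyr::pivot_wider(df[c("variant", "pool", "af")],
                                  names_from = "pool", values_from = "af")
    af <- as.matrix(af_wide[-1])
    rownames(af) <- af_wide$variant
    pools <- distinct(df[c("pool", "phenotype", "size", "depth")]) %>%
      arrange(.data$pool)
    if (anyDuplicated(pools$pool)) {
      stop_validation("inconsistent pool metadata across rows")
    }
    af <- af[, pools$pool, drop = FALSE]
    return(structure(list(af = af, pools = pools), class = "pool_af"))
  }

  if (schema == "annotations") {
    require_cols(df, c("variant", "regulome_score", "tf_or_dhs_overlap",
                       "ago_evidence_count"))
    cls <- suppressWarnings(as.integer(substr(df$regulome_score, 1, 1)))
    bad <- which(is.na(cls) | cls < 1 | cls > 7)
    if (length(bad)) {
      stop_validation(sprintf("invalid regulome score at row %d: %s", bad[1],
                              df$regulome_score[bad[1]]))
    }
    if (any(df$ago_evidence_count < 0)) {
      stop_validation("ago_evidence_count must be >= 0")
    }
    df$regulome_class <- cls
    if (!"coding_effect" %in% names(df)) df$coding_effect <- "none"
    return(as_tibble(df))
  }

  # results: generic, needs at least one p-value column
  if (!any(c("p_value", "p", "p_allelic") %in% names(df))) {
    stop_validation("results table lacks a p-value column")
  }
  as_tibble(df)
}

#' Write a result table as TSV with fixed p-value formatting
#'
#' P-value columns (`p`, `p_value`, `p_allelic`, `p_genotypic`, `p_adjust`)
#' are printed with four decimal places, matching the precision of the
#' published association tables; all other columns are written unchanged, in
#' their input order.
#'
#' @param results a data frame of homogeneous result records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  pcols <- intersect(c("p", "p_value", "p_allelic", "p_genotypic", "p_adjust",
                       "neg_log10_p"), names(results))
  out <- as_tibble(results)
  for (pc in setdiff(pcols, "neg_log10_p")) {
    out[[pc]] <- ifelse(is.na(out[[pc]]), NA_character_,
                        formatC(out[[pc]], format = "f", digits = 4))
  }
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}
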
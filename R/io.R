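#' Write a stage-stamped TSV
#'
#' All tabular exchange uses tab-separated files headed by a comment line
#' naming the producing stage and the configuration hash, so outputs are
#' self-describing.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param stage producing stage name.
#' @param config_hash hash string of the driving configuration.
#' @return `path`, invisibly.
#' @export
write_stage_tsv <- function(df, path, stage = "ergogwas", config_hash = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#ergogwas stage=%s config=%s", stage, config_hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a stage-stamped TSV
#'
#' @param path file written by [write_stage_tsv()] (a leading `#` comment
#'   line is skipped if present).
#' @return data.frame.
#' @export
read_stage_tsv <- function(path) {
  first <- readLines(path, n = 1)
  skip <- if (startsWith(first, "#")) 1L else 0L
  as.data.frame(data.table::fread(path, sep = "\t", skip = skip,
                                  header = TRUE, na.strings = "NA"))
}

#' Write genotype dosages as a minimal VCF v4.2
#'
#' One FORMAT field (`DS`, the a1 dosage in `[0, 2]`); the effect allele
#' a1 is written as ALT and a0 as REF, so dosages count ALT copies.
#'
#' @param genotypes a `genotype_matrix`.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  map <- genotypes$map
  dos <- genotypes$dosage
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ergogwas",
               paste0("##contig=<ID=", sort(unique(map$chrom)), ">"),
               paste0("##FORMAT=<ID=DS,Number=1,Type=Float,",
                      "Description=\"Estimated alternate allele dosage\">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(dos)), collapse = "\t")),
             con)
  body <- cbind(map$chrom, map$pos, map$variant_id, map$a0, map$a1,
                ".", "PASS", ".", "DS",
                matrix(formatC(dos, format = "g", digits = 10),
                       nrow(dos), ncol(dos)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write genotype dosages as a TSV matrix
#'
#' Columns chrom, pos, variant_id, a1, a0 followed by one dosage column
#' per sample.
#'
#' @inheritParams write_vcf
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- cbind(genotypes$map[, c("chrom", "pos", "variant_id", "a1", "a0")],
              as.data.frame(genotypes$dosage))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF files (parsed with vcfR) use the `DS` FORMAT field when present,
#' else hard-call `GT` genotypes converted to alternate-allele counts.
#' Dosage TSVs follow the [write_dosage_tsv()] layout. The returned object
#' orients a1 to ALT/the TSV's a1 column.
#'
#' @param path a `.vcf` (optionally gzipped) or `.tsv` file.
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    has_ds <- any(grepl("DS", v@gt[, "FORMAT"]))
    if (has_ds) {
      dos <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    } else {
      gt <- vcfR::extract.gt(v, element = "GT")
      dos <- matrix(vapply(strsplit(gsub("\\|", "/", gt), "/"),
                           function(x) sum(x == "1"), numeric(1)),
                    nrow(gt), ncol(gt), dimnames = dimnames(gt))
    }
    fix <- vcfR::getFIX(v)
    map <- data.frame(chrom = as.integer(fix[, "CHROM"]),
                      pos = as.integer(fix[, "POS"]),
                      variant_id = fix[, "ID"],
                      a1 = fix[, "ALT"], a0 = fix[, "REF"],
                      stringsAsFactors = FALSE)
    rownames(dos) <- map$variant_id
  } else {
    df <- as.data.frame(data.table::fread(path, sep = "\t"))
    meta <- c("chrom", "pos", "variant_id", "a1", "a0")
    .assert(all(meta %in% names(df)), "dosage TSV missing metadata columns")
    map <- df[, meta]
    dos <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
    rownames(dos) <- map$variant_id
  }
  structure(list(dosage = dos, map = map), class = "genotype_matrix")
}
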
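# Variant integration: a protein transmits signal only if its gene is both
# expressed and intact. Deleterious variants set a binary per-gene,
# per-sample integrity factor to 0, which multiplies the scaled expression
# value (the gene then behaves as a non-functional protein).

DELETERIOUS_CONSEQUENCES <- c("stop_gain", "stop_loss", "splicing_disrupting")
KNOWN_CONSEQUENCES <- c(DELETERIOUS_CONSEQUENCES,
                        "missense", "synonymous", "inframe_indel",
                        "frameshift", "UTR", "intronic", "intergenic",
                        "upstream", "downstream", "other")

#' Assemble a variant-call table
#'
#' @param sample,gene Character vectors.
#' @param consequence Consequence type string per call (e.g. `"stop_gain"`,
#'   `"missense"`).
#' @param sift SIFT-like pathogenicity score in \[0, 1\], *lower* is more
#'   damaging; `NA` when unavailable.
#' @param polyphen PolyPhen-like pathogenicity score in \[0, 1\], *higher* is
#'   more damaging; `NA` when unavailable.
#' @param conservation Conservation score (e.g. phastCons) in \[0, 1\],
#'   higher means more conserved; `NA` when unavailable.
#' @param zygosity `"het"` or `"hom"` per call.
#' @return `data.frame` of class `variant_calls`.
#' @export
variant_calls <- function(sample, gene, consequence,
                          sift = NA_real_, polyphen = NA_real_,
                          conservation = NA_real_, zygosity = "het") {
  df <- data.frame(sample = as.character(sample),
                   gene = as.character(gene),
                   consequence = as.character(consequence),
                   sift = as.numeric(sift),
                   polyphen = as.numeric(polyphen),
                   conservation = as.numeric(conservation),
                   zygosity = as.character(zygosity),
                   stringsAsFactors = FALSE)
  if (!all(df$zygosity %in% c("het", "hom"))) {
    stop("zygosity must be 'het' or 'hom'")
  }
  for (col in c("sift", "polyphen", "conservation")) {
    bad <- !is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 1)
    if (any(bad)) stop("'", col, "' scores outside [0, 1]")
  }
  class(df) <- c("variant_calls", "data.frame")
  df
}

#' Default score cutoffs for calling a variant damaging
#'
#' SIFT-like scores are damaging when small, PolyPhen-like when large, and a
#' damaging call additionally requires the site to be conserved. These are
#' the scores' conventional damaging ranges; all are configurable.
#'
#' @param sift_max Damaging when SIFT-like score <= this (default 0.05).
#' @param polyphen_min Damaging when PolyPhen-like score >= this (default
#'   0.85).
#' @param conservation_min Site considered conserved when score >= this
#'   (default 0.95).
#' @return Named list of cutoffs.
#' @export
integrity_thresholds <- function(sift_max = 0.05, polyphen_min = 0.85,
                                 conservation_min = 0.95) {
  list(sift_max = sift_max, polyphen_min = polyphen_min,
       conservation_min = conservation_min)
}

#' Compute per-gene, per-sample integrity factors from variant calls
#'
#' A call qualifies as deleterious when its consequence type is damaging per
#' se (stop gain, stop loss, splicing disrupting) or when a pathogenicity
#' score is beyond its cutoff (SIFT-like <= `sift_max` or PolyPhen-like >=
#' `polyphen_min`) *and* the site is conserved (>= `conservation_min`).
#' Under dominant inheritance a single qualifying call zeroes the gene in
#' that sample; under recessive inheritance a homozygous qualifying call, or
#' two distinct heterozygous qualifying calls in the same gene (compound
#' heterozygote; phasing is ignored), are required. Genes and samples
#' without calls keep integrity 1.
#'
#' @param calls A [variant_calls()] table.
#' @param genes,samples Universe of the returned matrix; defaults to the ids
#'   seen in `calls`.
#' @param thresholds See [integrity_thresholds()].
#' @param inheritance `"dominant"` or `"recessive"`.
#' @return Binary genes x samples matrix (1 = intact, 0 = knocked out).
#' @export
compute_integrity <- function(calls, genes = NULL, samples = NULL,
                              thresholds = integrity_thresholds(),
                              inheritance = c("dominant", "recessive")) {
  inheritance <- match.arg(inheritance)
  stopifnot(is.data.frame(calls))
  genes <- genes %||% unique(calls$gene)
  samples <- samples %||% unique(calls$sample)
  im <- matrix(1, nrow = length(genes), ncol = length(samples),
               dimnames = list(genes, samples))
  if (nrow(calls) == 0L) return(im)

  unknown <- setdiff(unique(calls$consequence), KNOWN_CONSEQUENCES)
  if (length(unknown)) {
    warning("unknown consequence type(s) treated as non-deleterious: ",
            paste(unknown, collapse = ", "))
  }
  per_se <- calls$consequence %in% DELETERIOUS_CONSEQUENCES
  pathogenic <- (!is.na(calls$sift) & calls$sift <= thresholds$sift_max) |
    (!is.na(calls$polyphen) & calls$polyphen >= thresholds$polyphen_min)
  conserved <- !is.na(calls$conservation) &
    calls$conservation >= thresholds$conservation_min
  qualifying <- per_se | (pathogenic & conserved)

  q <- calls[qualifying & calls$gene %in% genes & calls$sample %in% samples, ,
             drop = FALSE]
  if (nrow(q) == 0L) return(im)
  key <- paste(q$gene, q$sample, sep = "\r")
  if (inheritance == "dominant") {
    hit <- unique(key)
  } else {
    hom <- unique(key[q$zygosity == "hom"])
    het_counts <- table(key[q$zygosity == "het"])
    hit <- union(hom, names(het_counts)[het_counts >= 2L])
  }
  if (length(hit)) {
    parts <- strsplit(hit, "\r", fixed = TRUE)
    im[cbind(vapply(parts, `[[`, character(1), 1L),
             vapply(parts, `[[`, character(1), 2L))] <- 0
  }
  im
}

#' Multiply expression by integrity factors
#'
#' Genes or samples absent from the integrity matrix pass through unchanged
#' (default integrity 1). Applying the same integrity matrix twice equals
#' applying it once.
#'
#' @param m Numeric genes x samples expression matrix.
#' @param im Binary integrity matrix from [compute_integrity()].
#' @return Matrix of the same shape as `m`.
#' @export
apply_integrity <- function(m, im) {
  check_expression_matrix(m)
  g <- intersect(rownames(m), rownames(im))
  s <- intersect(colnames(m), colnames(im))
  if (length(g) && length(s)) {
    m[g, s] <- m[g, s] * im[g, s]
  }
  m
}

#' Read variant calls from a VCF or a call TSV
#'
#' The VCF reader (requires the `vcfR` package) extracts one call per
#' sample with a non-reference genotype per record. Gene, consequence and
#' score annotations are read from INFO keys named in `fields`; records
#' lacking a gene annotation are dropped with a warning. The TSV alternative
#' expects columns `sample`, `gene`, `consequence`, and optionally `sift`,
#' `polyphen`, `conservation`, `zygosity`.
#'
#' @param path File path (`.vcf` or TSV).
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param fields Named list mapping the annotation roles `gene`,
#'   `consequence`, `sift`, `polyphen`, `conservation` to INFO keys.
#' @return A [variant_calls()] table.
#' @export
read_variant_calls <- function(path, format = c("auto", "vcf", "tsv"),
                               fields = list(gene = "GENE",
                                             consequence = "CSQT",
                                             sift = "SIFT",
                                             polyphen = "POLYPHEN",
                                             conservation = "PHASTCONS")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
      "vcf"
    } else {
      "tsv"
    }
  }
  if (format == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("sample", "gene", "consequence")
    if (!all(need %in% names(df))) {
      stop("call TSV '", path, "' needs columns: ",
           paste(need, collapse = ", "))
    }
    return(variant_calls(df$sample, df$gene, df$consequence,
                         sift = df$sift %||% NA_real_,
                         polyphen = df$polyphen %||% NA_real_,
                         conservation = df$conservation %||% NA_real_,
                         zygosity = df$zygosity %||% "het"))
  }
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  info_of <- function(key) vcfR::extract.info(v, element = key)
  gene <- info_of(fields$gene)
  csq <- info_of(fields$consequence)
  sift <- suppressWarnings(as.numeric(info_of(fields$sift)))
  poly <- suppressWarnings(as.numeric(info_of(fields$polyphen)))
  cons <- suppressWarnings(as.numeric(info_of(fields$conservation)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF '", path, "' has no per-sample genotypes")

  keep <- !is.na(gene) & nzchar(gene)
  if (any(!keep)) {
    warning("VCF '", path, "': dropped ", sum(!keep),
            " record(s) without a '", fields$gene, "' INFO annotation")
  }
  out <- list()
  for (i in which(keep)) {
    alleles <- strsplit(gsub("\\|", "/", gt[i, ]), "/", fixed = TRUE)
    nalt <- vapply(alleles, function(a) sum(a != "0" & a != "."), integer(1))
    carriers <- names(nalt)[nalt > 0L & !is.na(nalt)]
    if (!length(carriers)) next
    out[[length(out) + 1L]] <- data.frame(
      sample = carriers, gene = gene[i],
      consequence = csq[i] %||% "other",
      sift = sift[i], polyphen = poly[i], conservation = cons[i],
      zygosity = ifelse(nalt[carriers] >= 2L, "hom", "het"),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(variant_calls(character(0), character(0), character(0)))
  }
  df <- do.call(rbind, out)
  df$consequence[is.na(df$consequence)] <- "other"
  variant_calls(df$sample, df$gene, df$consequence, df$sift, df$polyphen,
                df$conservation, df$zygosity)
}
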
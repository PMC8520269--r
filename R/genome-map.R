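# Coordinate conventions across this module:
#   GFF3         1-based inclusive (kept as-is)
#   PAF          0-based half-open target coordinates (shifted to 1-based
#                on input)
#   internal     1-based inclusive everywhere

#' Parse gene intervals from a GFF3 annotation
#'
#' Reads a GFF3 file and retains features of the requested type (default
#' `gene`) as 1-based inclusive intervals, taking the `ID` attribute (or
#' `Name` when `ID` is absent) as the gene identifier. Features lacking
#' both attributes are skipped with a warning.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature type(s) to keep from column 3.
#' @return Data frame: `seqid`, `start`, `end`, `strand`, `gene_id`.
#' @export
parse_gff <- function(path, feature_type = "gene") {
  if (!file.exists(path)) abort("GFF file not found: %s", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) abort("failed to parse GFF %s: %s",
                              path, conditionMessage(e))
  )
  gr <- gr[as.character(gr$type) %in% feature_type]
  if (!length(gr)) {
    warn("no '%s' features in %s", paste(feature_type, collapse = "/"), path)
    return(data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE))
  }
  meta <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(meta)) as.character(meta$ID) else
    rep(NA_character_, length(gr))
  nm <- if ("Name" %in% names(meta)) as.character(meta$Name) else
    rep(NA_character_, length(gr))
  gene_id <- ifelse(is.na(id) | id == "", nm, id)
  drop <- is.na(gene_id) | gene_id == ""
  if (any(drop)) {
    warn("%d feature(s) without ID/Name attribute skipped", sum(drop))
  }
  data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr))[!drop],
    start = GenomicRanges::start(gr)[!drop],
    end = GenomicRanges::end(gr)[!drop],
    strand = as.character(GenomicRanges::strand(gr))[!drop],
    gene_id = gene_id[!drop],
    stringsAsFactors = FALSE
  )
}

#' Parse a scaffold-to-chromosome mapping table
#'
#' Reads either a PAF alignment file (scaffolds mapped against a
#' chromosome-level assembly, e.g. Minimap2 output) or a pre-digested TSV,
#' and keeps the single best mapping per scaffold: highest mapping
#' quality, ties broken by longest alignment block, then by file order.
#' PAF target coordinates are 0-based half-open and are shifted to the
#' 1-based inclusive convention used internally.
#'
#' The TSV dialect (header required) has columns `scaffold`,
#' `scaffold_len`, `chromosome`, `chrom_start` (1-based), `orientation`
#' (`+`/`-`), `mapping_quality`.
#'
#' @param path Path to the mapping file.
#' @param dialect `"paf"` or `"tsv"`.
#' @return Data frame of class `scaffold_mapping`: `scaffold`,
#'   `scaffold_len`, `chromosome`, `chrom_start`, `orientation`,
#'   `mapping_quality`, one row per scaffold.
#' @export
parse_scaffold_map <- function(path, dialect = c("paf", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort("mapping file not found: %s", path)
  if (dialect == "paf") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    rows <- strsplit(lines, "\t", fixed = TRUE)
    short <- lengths(rows) < 12
    if (any(short)) {
      abort("PAF line %d has %d fields; at least 12 required",
            which(short)[1], lengths(rows)[short][1])
    }
    df <- data.frame(
      scaffold = vapply(rows, `[`, character(1), 1),
      scaffold_len = as.integer(vapply(rows, `[`, character(1), 2)),
      orientation = vapply(rows, `[`, character(1), 5),
      chromosome = vapply(rows, `[`, character(1), 6),
      chrom_start = as.integer(vapply(rows, `[`, character(1), 8)) + 1L,
      block_len = as.integer(vapply(rows, `[`, character(1), 11)),
      mapping_quality = as.integer(vapply(rows, `[`, character(1), 12)),
      stringsAsFactors = FALSE
    )
  } else {
    df <- read_tsv(path)
    need <- c("scaffold", "scaffold_len", "chromosome", "chrom_start",
              "orientation", "mapping_quality")
    missing <- setdiff(need, names(df))
    if (length(missing)) {
      abort("mapping TSV lacks column(s): %s", paste(missing, collapse = ", "))
    }
    df$block_len <- df$block_len %||% df$scaffold_len
  }
  if (!all(df$orientation %in% c("+", "-"))) {
    abort("orientation must be '+' or '-'")
  }
  # best mapping per scaffold: quality, then block length, then file order
  ord <- order(df$scaffold, -df$mapping_quality, -df$block_len,
               seq_len(nrow(df)))
  df <- df[ord, ]
  df <- df[!duplicated(df$scaffold), ]
  df <- df[order(df$scaffold), c("scaffold", "scaffold_len", "chromosome",
                                 "chrom_start", "orientation",
                                 "mapping_quality")]
  rownames(df) <- NULL
  class(df) <- c("scaffold_mapping", class(df))
  df
}

#' Lift a scaffold position to chromosome coordinates
#'
#' For a scaffold mapped in forward orientation,
#' `chrom_pos = chrom_start + scaffold_pos - 1`; in reverse orientation,
#' `chrom_pos = chrom_start + (scaffold_len - scaffold_pos)`. Both are
#' injective in `scaffold_pos`, so lifting is exactly invertible (see
#' [unlift_coordinates()]).
#'
#' @param scaffold Scaffold name(s).
#' @param scaffold_pos 1-based position(s) on the scaffold.
#' @param mapping A `scaffold_mapping` from [parse_scaffold_map()].
#' @return Data frame: `chromosome` (or `"UNPLACED"` for scaffolds without
#'   a mapping) and `chrom_pos` (`NA` when unplaced).
#' @export
lift_coordinates <- function(scaffold, scaffold_pos, mapping) {
  i <- match(scaffold, mapping$scaffold)
  placed <- !is.na(i)
  if (any(placed)) {
    len <- mapping$scaffold_len[i[placed]]
    pos <- scaffold_pos[placed]
    if (any(pos < 1 | pos > len)) {
      bad <- which(pos < 1 | pos > len)[1]
      abort("scaffold_pos %d out of range [1, %d] on scaffold %s",
            pos[bad], len[bad], scaffold[placed][bad])
    }
  }
  chrom <- rep("UNPLACED", length(scaffold))
  cpos <- rep(NA_integer_, length(scaffold))
  if (any(placed)) {
    m <- mapping[i[placed], ]
    fwd <- m$orientation == "+"
    p <- scaffold_pos[placed]
    cp <- numeric(length(p))
    cp[fwd] <- m$chrom_start[fwd] + p[fwd] - 1
    cp[!fwd] <- m$chrom_start[!fwd] + (m$scaffold_len[!fwd] - p[!fwd])
    chrom[placed] <- m$chromosome
    cpos[placed] <- as.integer(cp)
  }
  data.frame(chromosome = chrom, chrom_pos = cpos, stringsAsFactors = FALSE)
}

#' Invert a coordinate lift
#'
#' Recovers the scaffold position from a lifted chromosome position,
#' exactly inverting [lift_coordinates()].
#'
#' @param scaffold Scaffold name(s).
#' @param chrom_pos Lifted chromosome position(s).
#' @param mapping A `scaffold_mapping`.
#' @return Integer vector of 1-based scaffold positions.
#' @export
unlift_coordinates <- function(scaffold, chrom_pos, mapping) {
  i <- match(scaffold, mapping$scaffold)
  if (anyNA(i)) {
    abort("scaffold(s) not in mapping: %s",
          paste(unique(scaffold[is.na(i)]), collapse = ", "))
  }
  m <- mapping[i, ]
  fwd <- m$orientation == "+"
  out <- integer(length(scaffold))
  out[fwd] <- chrom_pos[fwd] - m$chrom_start[fwd] + 1L
  out[!fwd] <- m$scaffold_len[!fwd] - (chrom_pos[!fwd] - m$chrom_start[!fwd])
  out
}

#' Annotate outlier SNPs with chromosome coordinates and gene overlap
#'
#' Lifts each SNP's scaffold coordinate to chromosomes (where a mapping
#' exists) and flags SNPs whose lifted position falls within a gene
#' interval on the same chromosome (inclusive bounds). When a SNP overlaps
#' several genes, the gene with the lowest start coordinate wins — an
#' arbitrary but deterministic tie-break. Gene intervals are expected in
#' the same coordinate system as the lifted SNPs (i.e. annotations of the
#' chromosome-level assembly).
#'
#' @param snps Data frame with columns `locus`, `scaffold`, `scaffold_pos`,
#'   and the per-locus `alpha`/`beta` values to carry (e.g. an outlier
#'   table joined to locus coordinates).
#' @param genes Gene intervals from [parse_gff()] (seqid must name
#'   chromosomes).
#' @param mapping A `scaffold_mapping` from [parse_scaffold_map()].
#' @return Data frame of class `annotated_snps`: the input columns plus
#'   `chromosome`, `chrom_pos`, `in_gene`, `gene_id`.
#' @export
join_outliers_to_genes <- function(snps, genes, mapping) {
  need <- c("locus", "scaffold", "scaffold_pos")
  missing <- setdiff(need, names(snps))
  if (length(missing)) {
    abort("snps lacks column(s): %s", paste(missing, collapse = ", "))
  }
  lifted <- lift_coordinates(snps$scaffold, snps$scaffold_pos, mapping)
  out <- cbind(snps, lifted)
  out$in_gene <- FALSE
  out$gene_id <- NA_character_

  placed <- which(out$chromosome != "UNPLACED")
  if (length(placed) && nrow(genes)) {
    snp_gr <- GenomicRanges::GRanges(
      seqnames = out$chromosome[placed],
      ranges = IRanges::IRanges(start = out$chrom_pos[placed], width = 1))
    gene_gr <- GenomicRanges::GRanges(
      seqnames = genes$seqid,
      ranges = IRanges::IRanges(start = genes$start, end = genes$end))
    hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
    if (length(hits)) {
      h <- data.frame(q = S4Vectors::queryHits(hits),
                      s = S4Vectors::subjectHits(hits))
      h <- h[order(h$q, genes$start[h$s], h$s), ]
      h <- h[!duplicated(h$q), ]
      out$in_gene[placed[h$q]] <- TRUE
      out$gene_id[placed[h$q]] <- genes$gene_id[h$s]
    }
  }
  class(out) <- c("annotated_snps", class(out))
  out
}

#' Ideogram heatmap band table
#'
#' Converts annotated SNPs into the band table an ideogram renderer draws:
#' one band per placed SNP, centred on its lifted position, wide
#' (`gene_band_bp`) for SNPs inside known genes and narrow
#' (`nongene_band_bp`) for SNPs on surrounding scaffolds, clipped to the
#' chromosome bounds. The band's value is the SNP's cline parameter
#' (alpha or beta); rendering the conventional dual ideogram (alpha on the
#' left copy of each chromosome, beta on the right) is a presentation step
#' over two of these tables.
#'
#' @param annotated An `annotated_snps` table with `alpha`/`beta` columns
#'   (or whichever `param` names).
#' @param karyotype Data frame with columns `chromosome`, `length` (bp).
#' @param param Column of `annotated` to use as the band value.
#' @param gene_band_bp,nongene_band_bp Band widths in bp; the gene band
#'   must be the larger (defaults 2 Mb / 0.5 Mb, sized for turtle-scale
#'   chromosomes of tens to hundreds of Mb).
#' @return Data frame: `chromosome`, `band_start`, `band_end`, `value`,
#'   `locus`, `in_gene`.
#' @export
ideogram_bands <- function(annotated, karyotype, param = "alpha",
                           gene_band_bp = 2e6, nongene_band_bp = 5e5) {
  if (!(gene_band_bp > nongene_band_bp && nongene_band_bp > 0)) {
    abort("band widths must satisfy gene_band_bp > nongene_band_bp > 0")
  }
  if (!param %in% names(annotated)) {
    abort("column '%s' not found in annotated SNP table", param)
  }
  placed <- annotated[annotated$chromosome != "UNPLACED", , drop = FALSE]
  if (!nrow(placed)) {
    return(data.frame(chromosome = character(0), band_start = integer(0),
                      band_end = integer(0), value = numeric(0),
                      locus = character(0), in_gene = logical(0),
                      stringsAsFactors = FALSE))
  }
  ki <- match(placed$chromosome, karyotype$chromosome)
  if (anyNA(ki)) {
    abort("chromosome(s) absent from karyotype: %s",
          paste(unique(placed$chromosome[is.na(ki)]), collapse = ", "))
  }
  w <- ifelse(placed$in_gene, gene_band_bp, nongene_band_bp)
  start <- pmax(1, round(placed$chrom_pos - w / 2))
  end <- pmin(karyotype$length[ki], round(placed$chrom_pos + w / 2))
  data.frame(
    chromosome = placed$chromosome,
    band_start = as.numeric(start),
    band_end = as.numeric(end),
    value = placed[[param]],
    locus = placed$locus,
    in_gene = placed$in_gene,
    stringsAsFactors = FALSE
  )
}
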
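#' @name mutation_classes
#' @title Mutation class vocabulary
#' @description Closed set of somatic event classes understood by the
#'   package.  `hdel` / `hlamp` encode focal homozygous deletions and
#'   high-level amplifications derived from copy-number calls; `complex`
#'   marks a (patient, gene) pair that harboured several distinct mutation
#'   types before collapsing.
#' @format Character vector.
#' @export
mutation_classes <- c("missense", "nonsense", "frameshift_indel",
                      "inframe_indel", "splice_site", "synonymous",
                      "noncoding", "stop_gain", "hlamp", "hdel", "complex")

# classes excluded from impact modelling unless the user opts in
silent_classes <- c("synonymous", "noncoding")

# loss-of-function classes used by the tumour-suppressor counts
lof_classes <- c("nonsense", "stop_gain", "frameshift_indel", "splice_site")

# MAF Variant_Classification -> internal vocabulary
maf_class_map <- c(
  "Missense_Mutation" = "missense",
  "Nonsense_Mutation" = "nonsense",
  "Nonstop_Mutation" = "nonsense",
  "Frame_Shift_Del" = "frameshift_indel",
  "Frame_Shift_Ins" = "frameshift_indel",
  "In_Frame_Del" = "inframe_indel",
  "In_Frame_Ins" = "inframe_indel",
  "Splice_Site" = "splice_site",
  "Splice_Region" = "splice_site",
  "Translation_Start_Site" = "noncoding",
  "Silent" = "synonymous",
  "3'UTR" = "noncoding", "5'UTR" = "noncoding",
  "3'Flank" = "noncoding", "5'Flank" = "noncoding",
  "Intron" = "noncoding", "IGR" = "noncoding", "RNA" = "noncoding")

# normalise a raw record data frame into a collapsed mutation table
as_mutation_table <- function(df) {
  need <- c("patient", "gene", "mut_class")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_xshadow(paste0("missing required column(s): ",
                        paste(miss, collapse = ", ")),
                 "xshadow_format_error")
  if (nrow(df) == 0)
    stop_xshadow("mutation table is empty", "xshadow_empty_error")
  if (!"position" %in% names(df)) df$position <- NA_integer_
  df$position <- suppressWarnings(as.integer(df$position))
  df$patient <- as.character(df$patient)
  df$gene <- as.character(df$gene)
  df$mut_class <- as.character(df$mut_class)
  if (any(!nzchar(df$patient)) || any(!nzchar(df$gene)))
    stop_xshadow("patient and gene identifiers must be non-empty",
                 "xshadow_format_error")
  bad <- setdiff(unique(df$mut_class), mutation_classes)
  if (length(bad) > 0)
    stop_xshadow(paste0("unknown mutation class(es): ",
                        paste(bad, collapse = ", ")),
                 "xshadow_format_error")
  ## collapse multiple events of one (patient, gene) pair into one record;
  ## mixed mutation types become 'complex' and positions are dropped
  key <- paste(df$patient, df$gene, sep = "\r")
  if (anyDuplicated(key)) {
    parts <- split(seq_len(nrow(df)), key)
    rows <- lapply(parts, function(idx) {
      if (length(idx) == 1) return(df[idx, , drop = FALSE])
      cls <- unique(df$mut_class[idx])
      out <- df[idx[1], , drop = FALSE]
      out$mut_class <- if (length(cls) == 1) cls else "complex"
      out$position <- NA_integer_
      out
    })
    df <- do.call(rbind, rows)
  }
  df <- df[order(df$gene, df$patient), c("patient", "gene", "mut_class", "position")]
  rownames(df) <- NULL
  class(df) <- c("mutation_table", "data.frame")
  df
}

#' Read a somatic mutation table
#'
#' Reads tab-separated mutation records, either in the package's native
#' layout (`patient`, `gene`, `mut_class`, optional `position`) or a MAF-lite
#' layout (`Tumor_Sample_Barcode`, `Hugo_Symbol`, `Variant_Classification`,
#' optional `Protein_position`).  Multiple events on one (patient, gene) pair
#' are collapsed into a single record of class `"complex"`.  Synonymous and
#' noncoding records are retained in the table but are excluded from impact
#' modelling by default (see [xshadow_config()]).
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect `"tsv"` (native columns) or `"maf_lite"`.
#' @return A `mutation_table` data frame with one row per (patient, gene).
#' @export
read_mutations <- function(path, dialect = c("tsv", "maf_lite")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop_xshadow(paste0("file not found: ", path), "xshadow_io_error")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0)
    stop_xshadow("mutation file has no records", "xshadow_empty_error")
  if (dialect == "maf_lite") {
    need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0)
      stop_xshadow(paste0("missing required column(s): ",
                          paste(miss, collapse = ", ")),
                   "xshadow_format_error")
    cls <- maf_class_map[df$Variant_Classification]
    bad <- unique(df$Variant_Classification[is.na(cls)])
    if (length(bad) > 0)
      stop_xshadow(paste0("unmapped Variant_Classification value(s): ",
                          paste(bad, collapse = ", ")),
                   "xshadow_format_error")
    df <- data.frame(patient = df$Tumor_Sample_Barcode,
                     gene = df$Hugo_Symbol,
                     mut_class = unname(cls),
                     position = if ("Protein_position" %in% names(df))
                       suppressWarnings(as.integer(df$Protein_position))
                     else NA_integer_,
                     stringsAsFactors = FALSE)
  }
  as_mutation_table(df)
}

#' Read a patients-by-genes numeric matrix
#'
#' Layout: tab-separated, header row of gene identifiers, first column of
#' patient identifiers.  Used for both expression (log2 scale) and
#' copy-number (log2 ratio) matrices.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with patient row names and gene column names.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path))
    stop_xshadow(paste0("file not found: ", path), "xshadow_io_error")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop_xshadow("duplicate patient or gene identifiers in matrix",
                 "xshadow_format_error")
  m
}

#' @rdname read_expression_matrix
#' @export
read_copy_number <- read_expression_matrix

#' Read a weighted gene-gene influence graph
#'
#' Edge-list TSV with columns `gene_a`, `gene_b`, `weight`.  Self-loops are
#' dropped; duplicate edges for one unordered gene pair are merged keeping
#' the maximum weight, matching how networks from several sources are
#' combined into one prior-confidence graph.
#'
#' @param path Path to the edge-list TSV (or a data frame with the same
#'   columns).
#' @return An `influence_graph` data frame with one row per unordered pair.
#' @export
read_influence_graph <- function(path) {
  df <- if (is.data.frame(path)) path else {
    if (!file.exists(path))
      stop_xshadow(paste0("file not found: ", path), "xshadow_io_error")
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  need <- c("gene_a", "gene_b", "weight")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_xshadow(paste0("missing required column(s): ",
                        paste(miss, collapse = ", ")),
                 "xshadow_format_error")
  if (!is_prob(df$weight))
    stop_xshadow("edge weights must lie in [0, 1]", "xshadow_domain_error")
  df$gene_a <- as.character(df$gene_a); df$gene_b <- as.character(df$gene_b)
  df <- df[df$gene_a != df$gene_b, , drop = FALSE]
  if (nrow(df) == 0) {
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("influence_graph", "data.frame")
    return(out)
  }
  a <- pmin(df$gene_a, df$gene_b); b <- pmax(df$gene_a, df$gene_b)
  key <- paste(a, b, sep = "\r")
  w <- tapply(df$weight, key, max)
  ab <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
  out <- data.frame(gene_a = ab[, 1], gene_b = ab[, 2], weight = unname(w),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), ]
  rownames(out) <- NULL
  class(out) <- c("influence_graph", "data.frame")
  out
}

#' Encode copy-number calls as mutation events
#'
#' Focal homozygous deletions and high-level amplifications (four or more
#' copies) act like mutations for the trans analysis; this converts a
#' discrete call matrix into mutation records of class `hdel` / `hlamp`.
#'
#' @param calls Patients-by-genes matrix of discrete calls: `"hdel"`,
#'   `"neutral"` or `"hlamp"` (numeric -1 / 0 / 1 also accepted).
#' @return A `mutation_table` data frame; neutral calls yield no record.
#' @export
encode_cnv_events <- function(calls) {
  if (is.null(calls))
    stop_xshadow("a discrete call matrix is required", "xshadow_precondition_error")
  m <- as.matrix(calls)
  if (is.numeric(m)) {
    if (!all(m %in% c(-1, 0, 1)))
      stop_xshadow("numeric calls must be -1 (hdel), 0 (neutral) or 1 (hlamp)",
                   "xshadow_format_error")
    m[] <- c("hdel", "neutral", "hlamp")[m + 2]
  }
  if (!all(m %in% c("hdel", "neutral", "hlamp")))
    stop_xshadow("calls must be 'hdel', 'neutral' or 'hlamp'",
                 "xshadow_format_error")
  idx <- which(m != "neutral", arr.ind = TRUE)
  if (nrow(idx) == 0) {
    out <- data.frame(patient = character(0), gene = character(0),
                      mut_class = character(0), position = integer(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("mutation_table", "data.frame")
    return(out)
  }
  as_mutation_table(data.frame(patient = rownames(m)[idx[, 1]],
                               gene = colnames(m)[idx[, 2]],
                               mut_class = m[idx],
                               stringsAsFactors = FALSE))
}

#' Restrict all inputs to the common patient set
#'
#' Analyses require patients present in every supplied data type; this
#' intersects patient identifiers across the mutation table, the expression
#' matrix and (optionally) the copy-number matrix.
#'
#' @param mut `mutation_table`.
#' @param expr Expression matrix (patients x genes).
#' @param cn Optional copy-number matrix.
#' @return List with elements `mut`, `expr`, `cn` (NULL if not given) and
#'   `patients`, the common patient vector.
#' @export
align_cohort <- function(mut, expr, cn = NULL) {
  common <- intersect(unique(mut$patient), rownames(expr))
  if (!is.null(cn)) common <- intersect(common, rownames(cn))
  if (length(common) == 0)
    stop_xshadow("no patients shared by all inputs", "xshadow_cohort_error")
  message(sprintf("cohort: %d patients shared by all inputs", length(common)))
  mut2 <- mut[mut$patient %in% common, , drop = FALSE]
  rownames(mut2) <- NULL
  list(mut = mut2,
       expr = expr[common, , drop = FALSE],
       cn = if (is.null(cn)) NULL else cn[common, , drop = FALSE],
       patients = common)
}

#' Write fitted posteriors to tab-separated files
#'
#' Writes `gene_posteriors.tsv` (gene, P(D)), `mutation_posteriors.tsv`
#' (gene, patient, mutation class, P(F)) and, when regulation posteriors are
#' present, `neighbour_posteriors.tsv` (gene, patient, neighbour, P(G) for
#' down/neutral/up).  Values are written with full double precision so a
#' round-trip read reproduces them to 1e-12.
#'
#' @param fit An `xshadow` fit (or any list with the same posterior fields).
#' @param dir Output directory, created if missing.
#' @return Invisibly, the vector of files written.
#' @export
write_posteriors <- function(fit, dir) {
  if (nrow(fit$genes) == 0)
    stop_xshadow("no posteriors to write", "xshadow_empty_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  files <- character(0)

  g <- fit$genes
  gf <- file.path(dir, "gene_posteriors.tsv")
  utils::write.table(data.frame(gene = g$gene, n_mutations = g$n_mutations,
                                p_d = fmt(g$p_d)),
                     gf, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, gf)

  m <- fit$mutations
  mf <- file.path(dir, "mutation_posteriors.tsv")
  utils::write.table(data.frame(gene = m$gene, patient = m$patient,
                                mut_class = m$mut_class, p_f = fmt(m$p_f)),
                     mf, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, mf)

  if (!is.null(fit$regulation) && nrow(fit$regulation) > 0) {
    r <- fit$regulation
    rf <- file.path(dir, "neighbour_posteriors.tsv")
    utils::write.table(data.frame(gene = r$gene, patient = r$patient,
                                  neighbour = r$neighbour,
                                  p_down = fmt(r$p_down),
                                  p_neutral = fmt(r$p_neutral),
                                  p_up = fmt(r$p_up)),
                       rf, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, rf)
  }
  invisible(files)
}

#' Read posteriors written by [write_posteriors()]
#'
#' @param dir Directory containing the posterior TSV files.
#' @return List with data frames `genes`, `mutations` and (if present)
#'   `regulation`.
#' @export
read_posteriors <- function(dir) {
  out <- list(
    genes = utils::read.delim(file.path(dir, "gene_posteriors.tsv"),
                              stringsAsFactors = FALSE),
    mutations = utils::read.delim(file.path(dir, "mutation_posteriors.tsv"),
                                  stringsAsFactors = FALSE))
  rf <- file.path(dir, "neighbour_posteriors.tsv")
  if (file.exists(rf)) out$regulation <- utils::read.delim(rf, stringsAsFactors = FALSE)
  out
}

#' Write fitted conditional probabilities as key-value TSV
#'
#' @param params An [xshadow_params()] object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_theta <- function(params, path) {
  v <- c(theta_D = params$theta_D, theta_F1_D1 = params$theta_F1_D1,
         theta_F1_D0 = params$theta_F1_D0,
         stats::setNames(params$theta_G_F0,
                         paste0("theta_G_F0_", c("down", "neutral", "up"))),
         stats::setNames(params$theta_G_F1_up,
                         paste0("theta_G_F1_up_", c("down", "neutral", "up"))),
         stats::setNames(params$theta_G_F1_down,
                         paste0("theta_G_F1_down_", c("down", "neutral", "up"))))
  utils::write.table(data.frame(key = names(v),
                                value = formatC(v, digits = 17, format = "g")),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read conditional probabilities written by [write_theta()]
#'
#' @param path Key-value TSV file.
#' @return An [xshadow_params()] object.
#' @export
read_theta <- function(path) {
  kv <- utils::read.delim(path, stringsAsFactors = FALSE)
  v <- stats::setNames(as.numeric(kv$value), kv$key)
  xshadow_params(theta_D = v[["theta_D"]],
                 theta_F1_D1 = v[["theta_F1_D1"]],
                 theta_F1_D0 = v[["theta_F1_D0"]],
                 theta_G_F0 = unname(v[paste0("theta_G_F0_", c("down", "neutral", "up"))]),
                 theta_G_F1_up = unname(v[paste0("theta_G_F1_up_", c("down", "neutral", "up"))]),
                 theta_G_F1_down = unname(v[paste0("theta_G_F1_down_", c("down", "neutral", "up"))]))
}

#' Write an EM trace as TSV
#'
#' One row per iteration with the total log marginal likelihood and the EM
#' objective.
#'
#' @param em An `"xshadow_em"` object from [em_fit()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_em_trace <- function(em, path) {
  utils::write.table(data.frame(iteration = seq_along(em$loglik),
                                loglik = em$loglik,
                                objective = em$objective),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write fitted emission mixtures as TSV
#'
#' One row per (gene, component) with weight, location, scale and degrees of
#' freedom.
#'
#' @param mixtures Named list of `"tmixture"` objects (as stored in an
#'   `xshadow` fit).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_tmixtures <- function(mixtures, path) {
  rows <- lapply(names(mixtures), function(g) {
    m <- mixtures[[g]]
    data.frame(gene = g, component = c("down", "neutral", "up"),
               weight = unname(m$weight), loc = unname(m$loc),
               scale = unname(m$scale), df = unname(m$df))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
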
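## End-to-end orchestration: novelty filtering against known-site catalogs,
## per-sample variant accounting, the de novo / recessive / CNV / TEQ
## stages, and the summary report.

#' Partition variants by catalog membership
#'
#' Novelty filtering: variants present in the dbSNP-like catalog are
#' `shared_dbsnp`; of the rest, those present in the 1000G-like catalog are
#' `shared_1000g`; the remainder are `novel`.  The precedence makes the
#' partition exhaustive and disjoint, so per-category counts sum to the
#' input size.
#'
#' @param variants Trio variant data frame.
#' @param catalogs List with `known_sites` members `dbsnp_like` and
#'   `g1000_like` (either may be NULL).
#' @return Character vector over `{shared_dbsnp, shared_1000g, novel}`.
#' @export
filter_known <- function(variants, catalogs) {
  n <- nrow(variants)
  out <- rep("novel", n)
  if (n == 0L) return(out)
  key_in <- function(cat) {
    if (is.null(cat)) rep(FALSE, n)
    else in_catalog(cat, variants$contig, variants$pos, variants$ref,
                    variants$alt)
  }
  in_db <- key_in(catalogs$dbsnp_like)
  in_1k <- key_in(catalogs$g1000_like)
  out[in_1k] <- "shared_1000g"
  out[in_db] <- "shared_dbsnp"   # dbSNP precedence
  out
}

#' Pipeline run configuration
#'
#' Collects input paths, stage toggles and stage parameters, with
#' validation.  `file` may point to a JSON file with the same fields;
#' explicit arguments override file values.
#'
#' @param vcf,reference,genes,dbsnp,g1000,af_table,panel,depth,congeners
#'   Input paths (catalog/panel/depth/congener paths optional).
#' @param out_dir Output directory for the report files.
#' @param stages Character subset of `c("denovo", "recessive", "cnv",
#'   "teq")`.
#' @param min_dp,min_gq,edge_margin,max_af,alpha,n_permutations,min_width,
#'   genome_length,tef,nd_policy,seed Stage parameters.
#' @param file Optional JSON config file.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(vcf = NULL, reference = NULL, genes = NULL,
                       dbsnp = NULL, g1000 = NULL, af_table = NULL,
                       panel = NULL, depth = NULL, congeners = NULL,
                       out_dir = NULL,
                       stages = c("denovo", "recessive", "cnv", "teq"),
                       min_dp = 10L, min_gq = 20L, edge_margin = 10L,
                       max_af = 0.01, alpha = 0.01, n_permutations = 1000L,
                       min_width = 3L, genome_length = 3137161264,
                       tef = "WHO1998", nd_policy = "half", seed = 1L,
                       file = NULL) {
  cfg <- as.list(environment())
  cfg$file <- NULL
  if (!is.null(file)) {
    from_file <- read_json(file, simplifyVector = TRUE)
    given <- names(match.call())[-1]
    for (nm in setdiff(names(from_file), c(given, "file")))
      cfg[[nm]] <- from_file[[nm]]
  }
  bad <- setdiff(cfg$stages, c("denovo", "recessive", "cnv", "teq"))
  if (length(bad)) .stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  for (p in c("vcf", "reference", "genes", "dbsnp", "g1000", "af_table",
              "panel", "depth", "congeners")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      .stopf("input file for '%s' does not exist: %s", p, cfg[[p]])
  }
  if (!(cfg$max_af >= 0 && cfg$max_af <= 1 && cfg$alpha > 0 && cfg$alpha < 1))
    .stopf("parameter out of range (max_af in [0,1], alpha in (0,1))")
  structure(cfg, class = "run_config")
}

#' @noRd
table2_matrix <- function(v, partition) {
  samples <- c(father = "gt_father", mother = "gt_mother",
               proband = "gt_proband")
  types <- c(SNV = "SNV", indel = "indel")
  rows <- NULL
  for (ty in names(types)) {
    ty_sel <- if (ty == "SNV") v$vtype == "SNV"
              else v$vtype %in% c("insertion", "deletion")
    for (cat in c("total", "shared_dbsnp", "shared_1000g", "novel",
                  .REGION_LEVELS)) {
      cnt <- vapply(samples, function(col) {
        carrier <- gt_has_alt(v[[col]]) & ty_sel
        if (cat == "total") sum(carrier)
        else if (cat %in% c("shared_dbsnp", "shared_1000g"))
          sum(carrier & partition == cat)
        else if (cat == "novel") sum(carrier & partition == "novel")
        else sum(carrier & partition == "novel" & v$region == cat)
      }, 0L)
      rows <- rbind(rows, data.frame(type = ty, category = cat,
                                     father = cnt[["father"]],
                                     mother = cnt[["mother"]],
                                     proband = cnt[["proband"]],
                                     stringsAsFactors = FALSE))
    }
  }
  rows
}

#' Run the full prioritization pipeline
#'
#' Loads the trio VCF and companion inputs, annotates variants, partitions
#' them by catalog membership, and runs the enabled stages.  Writes
#' `report.json`, `table2.tsv`, `table3.tsv`, `segments.bed` and
#' `denovo.vcf` to `out_dir` when it is set.  A stage failure aborts the
#' run, names the failing stage, and removes partial outputs.
#'
#' @param cfg A `run_config`.
#' @return The summary report (list), invisibly writable as JSON.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  outputs <- character()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      suppressWarnings(file.remove(outputs[file.exists(outputs)]))
      .stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  env <- new.env()
  run_stage("io", {
    env$variants <- read_trio_vcf(cfg$vcf)
    env$reference <- if (!is.null(cfg$reference))
      as.character(read_reference(cfg$reference)) else NULL
    env$models <- if (!is.null(cfg$genes)) read_gene_models(cfg$genes)
                  else NULL
    env$af <- if (!is.null(cfg$af_table)) read_af_table(cfg$af_table)
              else NULL
    env$panel <- if (!is.null(cfg$panel)) read_known_sites(cfg$panel, "panel")
                 else NULL
    env$catalogs <- list(
      dbsnp_like = if (!is.null(cfg$dbsnp))
        read_known_sites(cfg$dbsnp, "dbSNP-like") else NULL,
      g1000_like = if (!is.null(cfg$g1000))
        read_known_sites(cfg$g1000, "1000G-like") else NULL)
  })

  run_stage("annotate", {
    env$ann <- annotate_variants(env$variants, env$reference, env$models,
                                 af_table = env$af)
  })

  report <- list(n_sites = nrow(env$ann))
  log <- list()

  run_stage("novelty", {
    env$partition <- filter_known(env$ann, env$catalogs)
    report$table2 <- table2_matrix(env$ann, env$partition)
    log$novelty <- table(env$partition)
  })

  if ("denovo" %in% cfg$stages) run_stage("denovo", {
    qc <- list(min_dp = cfg$min_dp, min_gq = cfg$min_gq)
    cand <- detect_denovo(env$ann, qc = qc, edge_margin = cfg$edge_margin)
    spec <- mutation_spectrum(cand, L = cfg$genome_length)
    env$denovo <- cand
    report$denovo <- list(
      n_candidates = nrow(cand),
      n_exonic = sum(cand$region == "exonic"),
      n_unevaluable = attr(cand, "unevaluable"),
      by_region = as.list(table(cand$region)),
      spectrum = unclass(spec))
  })

  if ("recessive" %in% cfg$stages) run_stage("recessive", {
    cht <- find_compound_het(env$ann, max_af = cfg$max_af, panel = env$panel)
    hom <- find_homozygous_recessive(env$ann, max_af = cfg$max_af,
                                     panel = env$panel)
    env$cht <- cht; env$hom <- hom
    report$compound_het <- list(
      n_genes = length(unique(cht$gene)), n_pairs = nrow(cht),
      calls = cht)
    report$hom_recessive <- list(
      n = nrow(hom),
      calls = if (nrow(hom)) hom[, c("contig", "pos", "ref", "alt", "gene",
                                     "effect", "aa_change")] else NULL)
  })

  if ("cnv" %in% cfg$stages && !is.null(cfg$depth)) run_stage("cnv", {
    d <- normalize_depth(read_depth_table(cfg$depth))
    set.seed(sub_seed(cfg$seed, "cnv"))
    segs <- segment_trio(d, alpha = cfg$alpha,
                         n_permutations = cfg$n_permutations,
                         min_width = cfg$min_width)
    segs <- classify_inheritance(call_copy_states(segs))
    env$segments <- segs
    hd <- segs[segs$state_proband == "hom_del", , drop = FALSE]
    report$cnv <- list(
      n_segments = nrow(segs),
      hom_del_proband = nrow(hd),
      hom_del_lengths_kb = sort((hd$end - hd$start) / 1000,
                                decreasing = TRUE),
      segments = segs)
  })

  if ("teq" %in% cfg$stages && !is.null(cfg$congeners)) run_stage("teq", {
    m <- read_congener_table(cfg$congeners)
    res <- compute_teq(m, scheme = cfg$tef, nd_policy = cfg$nd_policy)
    report$teq <- list(
      scheme = res$scheme, nd_policy = res$nd_policy,
      total = res$total,
      family_totals = res$family_totals,
      contributions = res$contributions)
  })

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(cfg$out_dir,
                       c("report.json", "table2.tsv", "table3.tsv",
                         "segments.bed", "denovo.vcf"))
    names(paths) <- c("report", "table2", "table3", "segments", "denovo")
    outputs <- paths
    run_stage("report", {
      write_json(report, paths["report"], auto_unbox = TRUE, digits = NA,
                 na = "null", pretty = TRUE)
      write.table(report$table2, paths["table2"], sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write.table(candidate_table(env), paths["table3"], sep = "\t",
                  quote = FALSE, row.names = FALSE)
      if (!is.null(env$segments)) {
        bed <- env$segments[, c("contig", "start", "end")]
        bed$name <- paste0("proband_", env$segments$state_proband, ";",
                           env$segments$inheritance)
        write.table(bed, paths["segments"], sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
      } else writeLines(character(), paths["segments"])
      if (!is.null(env$denovo)) write_trio_vcf(env$denovo, paths["denovo"])
      else writeLines(character(), paths["denovo"])
    })
    report$paths <- as.list(paths)
  }
  report
}

#' Combined candidate table (de novo exonic, compound het, homozygous
#' recessive, homozygous-deletion CNVs).
#' @noRd
candidate_table <- function(env) {
  out <- NULL
  add <- function(type, gene, contig, pos, ref, alt, detail) {
    rbind(out, data.frame(type = type, gene = gene, contig = contig,
                          pos = pos, ref = ref, alt = alt, detail = detail,
                          stringsAsFactors = FALSE))
  }
  if (!is.null(env$denovo)) {
    dn <- env$denovo[env$denovo$region == "exonic", , drop = FALSE]
    if (nrow(dn))
      out <- add("de_novo", dn$gene, dn$contig, dn$pos, dn$ref, dn$alt,
                 ifelse(is.na(dn$aa_change), dn$effect, dn$aa_change))
  }
  if (!is.null(env$cht) && nrow(env$cht)) {
    out <- add("compound_het", env$cht$gene, env$cht$contig,
               env$cht$pos_paternal, NA, NA,
               paste0(env$cht$aa_paternal, "/", env$cht$aa_maternal))
  }
  if (!is.null(env$hom) && nrow(env$hom)) {
    out <- add("hom_recessive", env$hom$gene, env$hom$contig, env$hom$pos,
               env$hom$ref, env$hom$alt, env$hom$aa_change)
  }
  if (!is.null(env$segments)) {
    hd <- env$segments[env$segments$state_proband == "hom_del", ,
                       drop = FALSE]
    if (nrow(hd))
      out <- add("homozygous_deletion", NA, hd$contig, hd$start, NA, NA,
                 sprintf("%d kb deletion (%s)",
                         round((hd$end - hd$start) / 1000), hd$inheritance))
  }
  if (is.null(out))
    out <- data.frame(type = character(), gene = character(),
                      contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      detail = character(), stringsAsFactors = FALSE)
  out
}
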
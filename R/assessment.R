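# Metric panel orchestration, ranking, report data --------------------------

#' Interaction network fidelity
#'
#' Geometric mean of precision and sensitivity of the model's interaction
#' set against the reference's: with TP the shared pairs, FP the model-only
#' pairs and FN the reference-only pairs,
#' INF = sqrt( TP/(TP+FP) * TP/(TP+FN) ). Both sets empty yields `NA`
#' (nothing to predict); an empty model set against a non-empty reference
#' yields 0.
#'
#' @param reference_set,model_set data.frames with residue-key columns
#'   `i`, `j` (unordered pairs).
#' @return value in `[0, 1]`, or `NA`.
#' @export
inf_score <- function(reference_set, model_set) {
  canon <- function(s) {
    if (NROW(s) == 0) return(character(0))
    unique(paste(pmin(s$i, s$j), pmax(s$i, s$j)))
  }
  r <- canon(reference_set); m <- canon(model_set)
  if (length(r) == 0 && length(m) == 0) return(NA_real_)
  tp <- length(intersect(r, m))
  if (tp == 0) return(0)
  sqrt((tp / length(m)) * (tp / length(r)))
}

# translate model-side interaction keys into reference keys via the mapping
# and drop interactions touching unmapped residues
restrict_translate <- function(iset, from_keys, to_keys) {
  tr <- function(s) {
    if (NROW(s) == 0) return(s)
    i2 <- to_keys[match(s$i, from_keys)]
    j2 <- to_keys[match(s$j, from_keys)]
    ok <- !is.na(i2) & !is.na(j2)
    data.frame(i = pmin(i2[ok], j2[ok]), j = pmax(i2[ok], j2[ok]),
               stringsAsFactors = FALSE)
  }
  list(wc = tr(iset$wc), nwc = tr(iset$nwc), stack = tr(iset$stack),
       all = tr(iset$all))
}

#' Assess one model against one or more references
#'
#' Runs the full metric panel per reference: residue mapping, interaction
#' sets restricted to mapped residues, RMSD, the four INF flavors, DI,
#' deformation profile (with optional domain aggregation), MCQ, and the
#' reference-independent clash score. The `best` element is the record
#' with minimal RMSD across references.
#'
#' @param model an `rna_structure`.
#' @param references one `rna_structure` or a list of them.
#' @param domains optional domain spec (see [resolve_domains()]), resolved
#'   against each reference.
#' @param config an [annotation_config()].
#' @param model_id,group_id,submitted_rank labels carried into the records.
#' @param strategy mapping strategy passed to [map_residues()].
#' @return object of class `assessment`: list with `records` (list of
#'   per-reference metric records) and `best`.
#' @export
assess_model <- function(model, references, domains = NULL,
                         config = annotation_config(),
                         model_id = model$id, group_id = NA,
                         submitted_rank = NA, strategy = "auto") {
  if (inherits(references, "rna_structure")) references <- list(references)
  if (length(references) == 0) stop("assess_model: need at least one reference")
  cs <- clash_score(nucleotide_only(model))
  records <- list(); failures <- character(0)
  model_sets_full <- interaction_sets(model, config)
  for (ref in references) {
    rec <- tryCatch(
      assess_one(model, ref, domains, config, model_id, group_id,
                 submitted_rank, cs, model_sets_full, strategy),
      error = function(e) e)
    if (inherits(rec, "error")) {
      failures <- c(failures, conditionMessage(rec))
    } else {
      records[[length(records) + 1]] <- rec
    }
  }
  if (length(records) == 0) {
    stop("assess_model: all references failed: ",
         paste(failures, collapse = "; "))
  }
  rmsds <- vapply(records, function(r) r$rmsd, numeric(1))
  structure(list(records = records, best = records[[which.min(rmsds)]]),
            class = "assessment")
}

assess_one <- function(model, ref, domains, config, model_id, group_id,
                       submitted_rank, cs, model_sets_full, strategy) {
  mapping <- map_residues(model, ref, strategy)
  mk <- mapping$pairs$model_key; rk <- mapping$pairs$ref_key
  msets <- restrict_translate(model_sets_full, mk, rk)
  rsets_full <- interaction_sets(ref, config)
  rsets <- restrict_translate(rsets_full, rk, rk)  # drop unmapped residues
  rmsd <- global_rmsd(model, ref, mapping)
  inf_all <- inf_score(rsets$all, msets$all)
  inf_wc <- inf_score(rsets$wc, msets$wc)
  inf_nwc <- inf_score(rsets$nwc, msets$nwc)
  inf_stack <- inf_score(rsets$stack, msets$stack)
  dp <- deformation_profile(model, ref, mapping)
  dp_domains <- NULL
  if (!is.null(domains)) {
    dom <- resolve_domains(domains, ref)
    dom <- lapply(dom, function(k) intersect(k, dp$residue_keys))
    dom <- dom[vapply(dom, length, 1L) > 0]
    if (length(dom) > 0) dp_domains <- aggregate_dp(dp, dom)
  }
  tm <- torsions(model, mk)
  tr <- torsions(ref, rk)
  mc <- mcq(tm, tr)
  list(model_id = model_id, group_id = group_id,
       submitted_rank = submitted_rank, reference_id = ref$id,
       rmsd = rmsd, di_all = deformation_index(rmsd, inf_all),
       inf_all = inf_all, inf_wc = inf_wc, inf_nwc = inf_nwc,
       inf_stack = inf_stack, mcq = mc$mcq, clash_score = cs$score,
       dp = dp, dp_domains = dp_domains, coverage = mapping$coverage)
}

#' @export
print.assessment <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "<assessment '%s'> best vs %s: RMSD %.3f A, DI %s, INF(all/wc/nwc/stack) %s/%s/%s/%s, MCQ %s, clash %s\n",
    b$model_id, b$reference_id, b$rmsd, fmt_na(b$di_all), fmt_na(b$inf_all),
    fmt_na(b$inf_wc), fmt_na(b$inf_nwc), fmt_na(b$inf_stack), fmt_na(b$mcq),
    fmt_na(b$clash_score)))
  invisible(x)
}

fmt_na <- function(x, digits = 3) {
  if (is.null(x) || is.na(x)) "NA" else formatC(x, digits = digits, format = "f")
}

METRIC_DIRECTIONS <- c(rmsd = 1, di_all = 1, mcq = 1, clash_score = 1,
                       inf_all = -1, inf_wc = -1, inf_nwc = -1,
                       inf_stack = -1, coverage = -1)

#' Rank models by one metric
#'
#' RMSD, DI, MCQ and clash score rank ascending (smaller is better); INF
#' flavors rank descending. `NA` values sink to the bottom. Ties are
#' broken by model id (lexicographic), so the ranking is a deterministic
#' total order regardless of input order.
#'
#' @param records list of metric records (e.g. `best` elements from
#'   [assess_model()]).
#' @param metric metric name.
#' @return data.frame `model_id`, `value`, `rank`, ordered best first.
#' @export
rank_models <- function(records, metric = "rmsd") {
  if (!metric %in% names(METRIC_DIRECTIONS)) {
    stop("rank_models: unknown metric '", metric, "'")
  }
  ids <- vapply(records, function(r) as.character(r$model_id), character(1))
  vals <- vapply(records, function(r) {
    v <- r[[metric]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  dir <- METRIC_DIRECTIONS[[metric]]
  ord <- order(is.na(vals), dir * vals, ids)
  data.frame(model_id = ids[ord], value = vals[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

RADAR_METRICS <- c("rmsd", "di_all", "inf_wc", "inf_nwc", "inf_stack",
                   "mcq", "clash_score")

#' Radar-rank data per group
#'
#' For each group, two vectors of relative ranks across the metric panel:
#' one for the group's first-submitted model (submitted_rank 1) and one
#' for its best-RMSD model. Ranks are computed among the selected models
#' of all groups; `NA` metrics sink last.
#'
#' @param records list of metric records carrying `group_id` and
#'   `submitted_rank`.
#' @return list with `first` and `best_rmsd`, each a data.frame of ranks
#'   (rows = groups, columns = metrics).
#' @export
radar_data <- function(records) {
  groups <- unique(vapply(records, function(r) as.character(r$group_id),
                          character(1)))
  rankless <- vapply(groups, function(g) {
    recs <- Filter(function(r) identical(as.character(r$group_id), g), records)
    !any(vapply(recs, function(r) !is.na(r$submitted_rank), TRUE))
  }, logical(1))
  if (any(rankless)) {
    warning("radar_data: group(s) lacking submitted_rank excluded: ",
            paste(groups[rankless], collapse = ", "))
    groups <- groups[!rankless]
  }
  pick <- function(sel_fun) {
    sel <- list()
    for (g in groups) {
      recs <- Filter(function(r) identical(as.character(r$group_id), g),
                     records)
      has_rank <- vapply(recs, function(r) !is.na(r$submitted_rank), TRUE)
      sel[[g]] <- sel_fun(recs[has_rank])
    }
    sel
  }
  first_sel <- pick(function(recs) {
    ranks <- vapply(recs, function(r) as.numeric(r$submitted_rank), numeric(1))
    recs[[which.min(ranks)]]
  })
  best_sel <- pick(function(recs) {
    recs[[which.min(vapply(recs, function(r) r$rmsd, numeric(1)))]]
  })
  rank_table <- function(sel) {
    gs <- names(sel)
    out <- matrix(NA_real_, length(gs), length(RADAR_METRICS),
                  dimnames = list(gs, RADAR_METRICS))
    if (length(gs) == 0) return(as.data.frame(out))
    for (m in RADAR_METRICS) {
      vals <- vapply(sel, function(r) {
        v <- r[[m]]; if (is.null(v)) NA_real_ else as.numeric(v)
      }, numeric(1))
      dir <- METRIC_DIRECTIONS[[m]]
      ord <- order(is.na(vals), dir * vals, gs)
      out[ord, m] <- seq_along(gs)
    }
    as.data.frame(out)
  }
  list(first = rank_table(first_sel), best_rmsd = rank_table(best_sel))
}

#' Per-residue mean B-factor profile
#'
#' Unweighted mean over heavy atoms, per nucleotide, in file order.
#' Intended to be displayed alongside DP heat maps: badly predicted
#' regions often coincide with high crystallographic mobility.
#'
#' @param reference an `rna_structure` (typically the crystal structure).
#' @param keys optional residue keys (default: all nucleotides).
#' @return data.frame `key`, `b_mean`.
#' @export
bfactor_profile <- function(reference, keys = NULL) {
  ri <- residue_table(reference)
  if (is.null(keys)) keys <- ri$key[ri$is_nt]
  b <- vapply(keys, function(k) {
    a <- residue_atoms(reference, k)
    mean(a$b[!a$is_h])
  }, numeric(1))
  data.frame(key = keys, b_mean = unname(b), stringsAsFactors = FALSE)
}

#' Summary table of assessments
#'
#' One row per (model, reference) record plus the per-model best row,
#' matching the report column convention: model, group, submitted_rank,
#' reference, RMSD, DI_all, INF_all, INF_wc, INF_nwc, INF_stack, MCQ,
#' Clash, coverage.
#'
#' @param assessments list of [assess_model()] results (or a single one).
#' @param best_only keep only each model's best-over-references record.
#' @return data.frame.
#' @export
summary_table <- function(assessments, best_only = FALSE) {
  if (inherits(assessments, "assessment")) assessments <- list(assessments)
  rows <- list()
  for (a in assessments) {
    recs <- if (best_only) list(a$best) else a$records
    for (r in recs) {
      rows[[length(rows) + 1]] <- data.frame(
        model = r$model_id, group = r$group_id,
        submitted_rank = r$submitted_rank, reference = r$reference_id,
        RMSD = r$rmsd, DI_all = na_or(r$di_all), INF_all = na_or(r$inf_all),
        INF_wc = na_or(r$inf_wc), INF_nwc = na_or(r$inf_nwc),
        INF_stack = na_or(r$inf_stack), MCQ = na_or(r$mcq),
        Clash = na_or(r$clash_score), coverage = r$coverage,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

na_or <- function(x) if (is.null(x) || is.na(x)) NA_real_ else x

#' Write a JSON assessment report
#'
#' One object per (model, reference) record plus a `best` object per
#' model. Undefined metrics are emitted as JSON null.
#'
#' @param assessments list of [assess_model()] results (or one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(assessments, path) {
  if (inherits(assessments, "assessment")) assessments <- list(assessments)
  strip <- function(r) {
    r$dp <- NULL
    if (!is.null(r$dp_domains)) r$dp_domains <- as.list(r$dp_domains)
    r
  }
  payload <- lapply(assessments, function(a) {
    list(records = lapply(a$records, strip), best = strip(a$best))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
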
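## Stage orchestration behind the command-line interface. Each stage
## reads its inputs from the run directory, writes its outputs plus a log
## line, and fails with a clear message naming any missing upstream
## artifact and the command that produces it.

.default_run_config <- function() {
  list(
    paths = list(bioactivity = NULL, alignment = NULL,
                 fingerprints = NULL, descriptors = NULL,
                 output = "gpcrmtl_run"),
    split = list(ratio = 0.8, seed = 1L, orphan_threshold = 8L),
    encoder = list(n_bits = 1024L, diameter = 6L, provider = "openbabel"),
    model = list(task = "mtl-ag-atg", folds = 5L, budget = 600,
                 fast = FALSE, seed = 1L, min_group = 4L),
    mrmr = list(grid = c(50L, 100L, 200L), threshold = 0.05, bins = 5L),
    probe = list(k = 7L, kind = "permutation", seed = 1L,
                 repetitions = 1L, cc_threshold = 0.95),
    ad = list(scope = "selected", threshold = 0.05),
    simulate = list(seed = 1L)
  )
}

#' Read and validate a run configuration
#'
#' A run configuration is a YAML file whose top-level sections are
#' \code{paths}, \code{split}, \code{encoder}, \code{model}, \code{mrmr},
#' \code{probe}, \code{ad} and \code{simulate}; omitted keys take the
#' package defaults and unknown keys are rejected.
#'
#' @param path YAML file, or \code{NULL} for the defaults.
#' @param overrides named list merged over the file values (used for
#'   command-line flag overrides; flags win over the file).
#' @return a validated \code{run_config} list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- .default_run_config()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  merge_into <- function(base, new, where) {
    unknown <- setdiff(names(new), names(base))
    if (length(unknown))
      stop("unknown config key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
    for (k in names(new)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(new[[k]]))
        merge_into(base[[k]], new[[k]], paste0(where, "$", k))
      else new[[k]]
    }
    base
  }
  cfg <- merge_into(cfg, user, "config")
  cfg <- merge_into(cfg, overrides, "overrides")
  structure(cfg, class = "run_config")
}

.out_path <- function(cfg, ...) file.path(cfg$paths$output, ...)

.need_artifact <- function(cfg, file, producer) {
  p <- .out_path(cfg, file)
  if (!file.exists(p))
    stop("missing input '", p, "'; run the '", producer,
         "' command first", call. = FALSE)
  p
}

.stage_log <- function(cfg, stage, started, notes = "") {
  line <- sprintf("%s\t%s\t%.1fs\tgpcrmtl %s\t%s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage,
                  as.numeric(difftime(Sys.time(), started, units = "secs")),
                  as.character(utils::packageVersion("gpcrmtl")), notes)
  cat(line, "\n", file = .out_path(cfg, "run.log"), append = TRUE)
  message(line)
}

.snapshot_config <- function(cfg) {
  yaml::write_yaml(unclass(cfg), .out_path(cfg, "config_snapshot.yaml"))
}

#' Run a pipeline stage
#'
#' Executes one named stage of the EC50 modelling pipeline against a run
#' configuration. Stages: \code{simulate} (synthetic fixtures into the
#' run directory), \code{encode} (load bioactivity + alignment + ligand
#' features, assemble the feature matrix, make the split), \code{select}
#' (mRMR ranking, budget curve, reduced matrix), \code{train} (fit the
#' configured task), \code{probe} (truncation and permutation reports),
#' \code{ad} (similarity matrix and applicability-domain report),
#' \code{evaluate} (validation and orphan metrics) and \code{report}
#' (collated per-task metric table).
#'
#' @param stage stage name.
#' @param cfg a \code{run_config} from [read_run_config()].
#' @return the stage's main result, invisibly (also written to the run
#'   directory).
#' @export
run_stage <- function(stage = c("simulate", "encode", "select", "train",
                                "probe", "ad", "evaluate", "report"),
                      cfg) {
  stage <- match.arg(stage)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$paths$output, recursive = TRUE, showWarnings = FALSE)
  .snapshot_config(cfg)
  started <- Sys.time()
  res <- switch(stage,
    simulate = .stage_simulate(cfg),
    encode = .stage_encode(cfg),
    select = .stage_select(cfg),
    train = .stage_train(cfg),
    probe = .stage_probe(cfg),
    ad = .stage_ad(cfg),
    evaluate = .stage_evaluate(cfg),
    report = .stage_report(cfg))
  .stage_log(cfg, stage, started)
  invisible(res)
}

.stage_simulate <- function(cfg) {
  ds <- generate_synthetic_dataset(seed = cfg$simulate$seed)
  paths <- write_fixtures(ds, cfg$paths$output)
  message("simulated ", nrow(ds$records), " records for ",
          nrow(ds$codes), " receptors")
  paths
}

.stage_encode <- function(cfg) {
  bio <- cfg$paths$bioactivity %||% .out_path(cfg, "bioactivity.tsv")
  aln <- cfg$paths$alignment %||% .out_path(cfg, "alignment.fasta")
  for (p in c(bio, aln)) if (!file.exists(p))
    stop("missing input '", p,
         "'; point paths$bioactivity/alignment at your data or run ",
         "'simulate'", call. = FALSE)
  records <- load_bioactivity_table(bio)
  parts <- split_orphan_receptors(records,
                                  cfg$split$orphan_threshold)
  split <- stratified_split(parts$modelled, ratio = cfg$split$ratio,
                            seed = cfg$split$seed,
                            orphan_test = parts$orphan)
  split$orphan_threshold <- cfg$split$orphan_threshold
  codes <- encode_alignment(read_alignment(aln))

  fp_path <- cfg$paths$fingerprints %||% {
    p <- .out_path(cfg, "ligand_fingerprints.tsv")
    if (file.exists(p)) p else NULL
  }
  if (!is.null(fp_path)) {
    tab <- utils::read.table(fp_path, header = TRUE, sep = "\t",
                             check.names = FALSE)
    rownames(tab) <- tab$ligand_id
    fp <- as.matrix(tab[, setdiff(names(tab), "ligand_id"), drop = FALSE])
  } else {
    got <- compute_fingerprints(records, n_bits = cfg$encoder$n_bits,
                                diameter = cfg$encoder$diameter)
    if (length(got$failed))
      warning("dropping ", length(got$failed),
              " ligands with unparsable SMILES")
    records <- records[records$ligand_id %in% rownames(got$fingerprints), ]
    fp <- got$fingerprints
  }
  de_path <- cfg$paths$descriptors %||% {
    p <- .out_path(cfg, "ligand_descriptors.tsv")
    if (file.exists(p)) p else NULL
  }
  desc <- if (!is.null(de_path)) {
    tab <- utils::read.table(de_path, header = TRUE, sep = "\t",
                             check.names = FALSE)
    compute_descriptors(records, provider = "precomputed",
                        table = tab)$descriptors
  } else {
    compute_descriptors(records, provider = cfg$encoder$provider)$descriptors
  }

  used <- rbind(split$train, split$validation, split$orphan_test)
  fm <- assemble_features(used, codes, fp, desc)
  state <- list(fm = fm, split = split, codes = codes)
  saveRDS(state, .out_path(cfg, "encoded.rds"))
  state
}

.stage_select <- function(cfg) {
  state <- readRDS(.need_artifact(cfg, "encoded.rds", "encode"))
  fm_tr <- subset_records(state$fm, state$split$train$record_id)
  fm_va <- subset_records(state$fm, state$split$validation$record_id)
  ranking <- mrmr_rank(fm_tr, m = max(cfg$mrmr$grid), bins = cfg$mrmr$bins)
  curve <- budget_curve(fm_tr, fm_va, ranking, grid = cfg$mrmr$grid,
                        specs = default_learners(fast = cfg$model$fast),
                        folds = cfg$model$folds, seed = cfg$model$seed)
  m <- choose_feature_budget(curve, threshold = cfg$mrmr$threshold)
  fm_sel <- apply_selection(state$fm, ranking, m)

  rk <- cbind(ranking,
              state$fm$provenance[ranking$column,
                                  c("block", "within_block_index")])
  utils::write.table(rk, .out_path(cfg, "mrmr_ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(curve, .out_path(cfg, "budget_curve.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  saveRDS(list(fm = fm_sel, ranking = ranking, chosen_m = m,
               curve = curve), .out_path(cfg, "selected.rds"))
  message("chose m = ", m, "; retained feature count = ",
          attr(fm_sel, "selected_count"))
  list(chosen_m = m, curve = curve)
}

.task_mode <- function(task)
  switch(task, "mtl-ag" = "agonist", "mtl-atg" = "antagonist",
         "mtl-ag-atg" = "merged", "stl" = NA_character_,
         stop("unknown task '", task, "'"))

.stage_train <- function(cfg) {
  state <- readRDS(.need_artifact(cfg, "encoded.rds", "encode"))
  sel <- .out_path(cfg, "selected.rds")
  fm <- if (file.exists(sel)) readRDS(sel)$fm else state$fm
  specs <- default_learners(fast = cfg$model$fast)
  task <- cfg$model$task
  if (task == "stl") {
    model <- train_single_task(fm, state$split, mode_filter = "agonist",
                               min_group = cfg$model$min_group,
                               specs = specs, folds = cfg$model$folds,
                               seed = cfg$model$seed,
                               time_budget = cfg$model$budget)
  } else {
    model <- train_multitask(fm, state$split,
                             mode_filter = .task_mode(task),
                             specs = specs, folds = cfg$model$folds,
                             seed = cfg$model$seed,
                             time_budget = cfg$model$budget)
  }
  saveRDS(list(model = model, task = task), .out_path(cfg, "model.rds"))
  model
}

.load_model_state <- function(cfg) {
  state <- readRDS(.need_artifact(cfg, "encoded.rds", "encode"))
  bundle <- readRDS(.need_artifact(cfg, "model.rds", "train"))
  sel <- .out_path(cfg, "selected.rds")
  fm <- if (file.exists(sel)) readRDS(sel)$fm else state$fm
  list(state = state, model = bundle$model, task = bundle$task, fm = fm)
}

.stage_evaluate <- function(cfg) {
  ms <- .load_model_state(cfg)
  if (ms$task == "stl") stop("evaluate expects a multitask model")
  rep_val <- evaluate_model(ms$model, ms$fm, ms$state$split, "validation")
  out <- rep_val$per_group
  out$partition <- "validation"
  if (nrow(ms$state$split$orphan_test) > 0) {
    rep_orp <- evaluate_model(ms$model, ms$fm, ms$state$split,
                              "orphan_test")
    og <- rep_orp$per_group
    og$partition <- "orphan_test"
    out <- rbind(out, og)
  }
  utils::write.table(out, .out_path(cfg, "evaluation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  preds <- attr(rep_val, "predictions")
  utils::write.table(preds, .out_path(cfg, "predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  saveRDS(rep_val, .out_path(cfg, "evaluation.rds"))
  rep_val
}

.stage_probe <- function(cfg) {
  ms <- .load_model_state(cfg)
  if (!file.exists(.out_path(cfg, "evaluation.rds")))
    .stage_evaluate(cfg)
  rep_val <- readRDS(.out_path(cfg, "evaluation.rds"))
  receptors <- select_probe_receptors(rep_val, cfg$probe$cc_threshold)
  if (length(receptors) == 0L)
    stop("no receptor passes the CC > ", cfg$probe$cc_threshold,
         " probe filter")
  L <- ms$fm$blocks[["protein"]]
  ## segments are defined over the original alignment positions even for
  ## a feature-selected matrix
  L_full <- max(ms$fm$provenance$within_block_index[
    ms$fm$provenance$block == "protein"])
  segments <- segment_protein_columns(L_full, cfg$probe$k)
  report <- if (cfg$probe$kind == "truncation")
    truncation_test(ms$model, ms$fm, ms$state$split, segments, receptors)
  else
    permutation_test(ms$model, ms$fm, ms$state$split, segments, receptors,
                     seed = cfg$probe$seed,
                     repetitions = cfg$probe$repetitions)
  utils::write.table(report, .out_path(cfg, "probe_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report
}

.stage_ad <- function(cfg) {
  state <- readRDS(.need_artifact(cfg, "encoded.rds", "encode"))
  codes <- state$codes
  cols <- seq_len(ncol(codes))
  if (cfg$ad$scope == "selected") {
    sel <- .out_path(cfg, "selected.rds")
    if (file.exists(sel)) {
      prov <- readRDS(sel)$fm$provenance
      cols <- prov$within_block_index[prov$block == "protein"]
    }
  }
  train_ids <- unique(state$split$train$receptor_id)
  orphan_ids <- unique(state$split$orphan_test$receptor_id)
  sim <- pairwise_similarity_matrix(codes, cols, scope = cfg$ad$scope)
  long <- data.frame(
    receptor_i = rep(rownames(sim$ts), times = ncol(sim$ts)),
    receptor_j = rep(colnames(sim$ts), each = nrow(sim$ts)),
    scope = cfg$ad$scope, ts = as.numeric(sim$ts))
  long <- long[long$receptor_i < long$receptor_j, ]
  utils::write.table(long, .out_path(cfg, "similarity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  res <- NULL
  if (length(orphan_ids)) {
    res <- ad_filter(codes[orphan_ids, , drop = FALSE],
                     codes[train_ids, , drop = FALSE],
                     threshold = cfg$ad$threshold, columns = cols)
    with_dec <- function(d, v)
      data.frame(d, decision = rep(v, nrow(d)), stringsAsFactors = FALSE)
    dec <- rbind(with_dec(res$retained, "retained"),
                 with_dec(res$excluded, "excluded"))
    dec$threshold <- cfg$ad$threshold
    utils::write.table(dec, .out_path(cfg, "ad_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(similarity = sim, ad = res)
}

.stage_report <- function(cfg) {
  ev <- .need_artifact(cfg, "evaluation.tsv", "evaluate")
  tab <- utils::read.table(ev, header = TRUE, sep = "\t")
  summ <- do.call(rbind, lapply(split(tab, tab$partition), function(d)
    data.frame(partition = d$partition[1], n_groups = nrow(d),
               n_records = sum(d$n), mean_mse = mean(d$mse),
               mean_cc = mean(d$cc[d$cc_defined], na.rm = TRUE))))
  utils::write.table(summ, .out_path(cfg, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message(paste(utils::capture.output(print(summ)), collapse = "\n"))
  summ
}
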
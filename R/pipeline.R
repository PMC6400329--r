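# Pipeline orchestration: one configuration object, one stage function per
# subcommand (synth, preprocess, embed, graph, scan, select, evaluate,
# report), artifacts on disk between stages. Every stage writes a sidecar
# meta file recording the configuration hash, the master seed and the
# package version, and appends a line to a structured log.

.pipeline_defaults <- function() {
  list(
    corpus = NULL,            # input corpus path (jsonl or csv)
    workdir = "ms_work",
    method = "pvdbow",        # or "tfidf"
    dim = 300L, epochs = 10L, window = 15L, min_count = 5L,
    negative = 5L, subsample = 0.001, infer_epochs = 50L,
    tfidf_min_count = 1L, tfidf_smooth = TRUE,
    stoplist_path = NULL, extra_excluded_verbs = character(0),
    stop_match = "both",
    k = 13L,
    t_min = 0.01, t_max = 100, n_times = 200L, grid = "log",
    n_runs = 500L, n_top = 50L,
    plateau_eps = 0.05, dip_quantile = 0.25, min_plateau = 3L,
    top_n_words = 10L, n_top_ngrams = 20L,
    master_seed = 1L,
    synth_spec = list()       # overrides for topic_spec() used by `synth`
  )
}

#' Pipeline configuration
#'
#' Builds the configuration for [run_pipeline()] from package defaults, an
#' optional YAML file, and direct overrides (precedence: arguments >
#' file > defaults). Unknown keys are rejected. The defaults are the
#' method's standard operating point: 300-dimensional paragraph vectors,
#' 10 epochs, window 15, minimum count 5, 5 negative samples, subsampling
#' 1e-3, MST-kNN with k = 13, 500 Louvain runs per Markov time keeping
#' the top 50.
#'
#' @param file optional YAML configuration file.
#' @param ... individual key overrides.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(file = NULL, ...) {
  cfg <- .pipeline_defaults()
  if (!is.null(file)) {
    loaded <- yaml::read_yaml(file)
    unknown <- setdiff(names(loaded), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(loaded)] <- loaded
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

# polynomial rolling hash of the canonicalised configuration, 8 hex digits
# (kept below 2^31 so arithmetic stays exact in doubles)
.config_hash <- function(cfg) {
  keys <- sort(setdiff(names(cfg), "workdir"))
  s <- paste(vapply(keys, function(k)
    paste0(k, "=", paste(deparse(cfg[[k]]), collapse = "")), character(1)),
    collapse = ";")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.artifact <- function(cfg, name) file.path(cfg$workdir, name)

.require_artifact <- function(cfg, name, produced_by) {
  p <- .artifact(cfg, name)
  if (!file.exists(p))
    stop(sprintf("missing artifact '%s'; run the '%s' stage first",
                 name, produced_by), call. = FALSE)
  p
}

.write_meta <- function(cfg, stage, elapsed) {
  meta <- list(stage = stage, config_hash = .config_hash(cfg),
               master_seed = cfg$master_seed,
               package_version = as.character(utils::packageVersion("mstopics")))
  jsonlite::write_json(meta, .artifact(cfg, paste0(stage, ".meta.json")),
                       auto_unbox = TRUE)
  log_line <- sprintf("stage=%s hash=%s seed=%d elapsed=%.2fs",
                      stage, meta$config_hash, cfg$master_seed, elapsed)
  cat(log_line, "\n", file = .artifact(cfg, "pipeline.log"), append = TRUE)
  invisible(NULL)
}

.run_stage <- function(cfg, stage, fn) {
  dir.create(cfg$workdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  out <- fn()
  .write_meta(cfg, stage, proc.time()[["elapsed"]] - t0)
  invisible(out)
}

#' Generate a synthetic corpus into the working directory
#'
#' Writes `corpus.jsonl` (id, text, category = super-topic) and
#' `labels.csv` (id, sub, super).
#'
#' @param cfg a [pipeline_config()]; `synth_spec` entries override the
#'   [topic_spec()] defaults, and the spec seed defaults to
#'   `master_seed`.
#' @return invisibly, the generated corpus path.
#' @export
pipeline_synth <- function(cfg) {
  .run_stage(cfg, "synth", function() {
    args <- cfg$synth_spec
    if (is.null(args$seed)) args$seed <- cfg$master_seed
    gen <- generate_corpus(do.call(topic_spec, args))
    write_corpus_jsonl(gen$corpus, .artifact(cfg, "corpus.jsonl"))
    utils::write.csv(data.frame(id = gen$corpus$id,
                                sub = unname(gen$sub_labels),
                                super = unname(gen$super_labels)),
                     .artifact(cfg, "labels.csv"), row.names = FALSE)
    .artifact(cfg, "corpus.jsonl")
  })
}

#' Preprocess the corpus
#'
#' Reads the input corpus (the `corpus` config path, or the synthetic
#' `corpus.jsonl` in the working directory), normalises it and writes
#' `tokens.jsonl`.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the tokens artifact path.
#' @export
pipeline_preprocess <- function(cfg) {
  .run_stage(cfg, "preprocess", function() {
    src <- if (!is.null(cfg$corpus)) cfg$corpus
    else .require_artifact(cfg, "corpus.jsonl", "synth")
    corp <- read_corpus(src)
    stoplist <- if (!is.null(cfg$stoplist_path))
      readLines(cfg$stoplist_path, warn = FALSE) else stopwords_en()
    corp <- preprocess_corpus(corp, stoplist = stoplist,
                              extra_excluded_verbs = cfg$extra_excluded_verbs,
                              stop_match = cfg$stop_match)
    write_tokens_jsonl(corp, .artifact(cfg, "tokens.jsonl"))
    if (!is.null(corp$category))
      utils::write.csv(data.frame(id = corp$id, category = corp$category),
                       .artifact(cfg, "categories.csv"), row.names = FALSE)
    .artifact(cfg, "tokens.jsonl")
  })
}

.read_tokens <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  ids <- vapply(recs, function(r) as.character(r$id), character(1))
  toks <- lapply(recs, function(r) as.character(r$tokens))
  sumtoks <- lapply(recs, function(r) as.character(r$summary_tokens))
  names(toks) <- ids
  names(sumtoks) <- ids
  list(ids = ids, tokens = toks, summary_tokens = sumtoks)
}

#' Embed the tokenised corpus
#'
#' Trains the configured embedding (`pvdbow` or `tfidf`) on
#' `tokens.jsonl` and writes the document vectors to `vectors.csv`.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the vectors artifact path.
#' @export
pipeline_embed <- function(cfg) {
  .run_stage(cfg, "embed", function() {
    tk <- .read_tokens(.require_artifact(cfg, "tokens.jsonl", "preprocess"))
    if (cfg$method == "pvdbow") {
      ecfg <- embedding_config(method = "pvdbow", dim = cfg$dim,
                               epochs = cfg$epochs, window = cfg$window,
                               min_count = cfg$min_count,
                               negative = cfg$negative,
                               subsample = cfg$subsample,
                               seed = cfg$master_seed)
      model <- train_embedding(tk$tokens, ecfg)
      vec <- infer_vectors(model, tk$tokens, epochs = cfg$infer_epochs,
                           seed = cfg$master_seed)
    } else {
      vec <- tfidf_vectors(tk$tokens, min_count = cfg$tfidf_min_count,
                           smooth = cfg$tfidf_smooth)
    }
    write_vectors_csv(vec, .artifact(cfg, "vectors.csv"))
    .artifact(cfg, "vectors.csv")
  })
}

#' Build the MST-kNN similarity graph
#'
#' Reads `vectors.csv`, computes the normalised similarity matrix and the
#' MST-kNN graph with the configured `k`, and writes `edges.tsv` and
#' `graph.graphml`.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the edge-list artifact path.
#' @export
pipeline_graph <- function(cfg) {
  .run_stage(cfg, "graph", function() {
    vec <- read_vectors_csv(.require_artifact(cfg, "vectors.csv", "embed"))
    G <- mst_knn(similarity_matrix(vec), k = cfg$k)
    write_edgelist(G, .artifact(cfg, "edges.tsv"))
    write_graphml(G, .artifact(cfg, "graph.graphml"))
    .artifact(cfg, "edges.tsv")
  })
}

.read_graph <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"))
  ids <- sort(unique(c(df$id_u, df$id_v)))
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  A[cbind(df$id_u, df$id_v)] <- df$weight
  A[cbind(df$id_v, df$id_u)] <- df$weight
  ms_graph(A, ids)
}

#' Run the Markov Stability scan
#'
#' Reads `edges.tsv`, scans the configured Markov-time grid, and writes
#' `scan.csv` (per-time diagnostics), `partitions.csv` (optimal
#' membership per time) and `vi_cross.csv`.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the scan artifact path.
#' @export
pipeline_scan <- function(cfg) {
  .run_stage(cfg, "scan", function() {
    G <- .read_graph(.require_artifact(cfg, "edges.tsv", "graph"))
    times <- if (identical(cfg$grid, "auto"))
      auto_time_grid(G, n = cfg$n_times, t_min = cfg$t_min)
    else ms_time_grid(cfg$t_min, cfg$t_max, cfg$n_times, cfg$grid)
    res <- ms_scan(G, times, n_runs = cfg$n_runs, n_top = cfg$n_top,
                   seed = cfg$master_seed)
    write_scan_csv(res, .artifact(cfg, "scan.csv"))
    P <- do.call(cbind, res$memberships)
    colnames(P) <- sprintf("t%03d", seq_along(res$times))
    utils::write.csv(cbind(data.frame(id = res$ids), P),
                     .artifact(cfg, "partitions.csv"), row.names = FALSE)
    utils::write.csv(res$vi_cross, .artifact(cfg, "vi_cross.csv"),
                     row.names = FALSE)
    .artifact(cfg, "scan.csv")
  })
}

.read_scan <- function(cfg) {
  sc <- utils::read.csv(.require_artifact(cfg, "scan.csv", "scan"))
  pt <- utils::read.csv(.require_artifact(cfg, "partitions.csv", "scan"),
                        colClasses = "character")
  vc <- as.matrix(utils::read.csv(.require_artifact(cfg, "vi_cross.csv",
                                                    "scan")))
  ids <- pt$id
  memberships <- lapply(seq_len(nrow(sc)), function(i)
    as_partition(as.integer(pt[[i + 1L]])))
  structure(list(times = sc$t, memberships = memberships, r_best = sc$r,
                 n_comms = sc$n_comms, vi_ensemble = sc$vi_ensemble,
                 vi_cross = unname(vc), ids = ids,
                 n_runs = cfg$n_runs, n_top = cfg$n_top,
                 seed = cfg$master_seed),
            class = "ms_scan_result")
}

#' Select robust scales from the scan artifacts
#'
#' Writes `selected.csv` (time, community count, plateau length) and
#' `memberships.csv` (id by selected scale).
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the selected-scales artifact path.
#' @export
pipeline_select <- function(cfg) {
  .run_stage(cfg, "select", function() {
    res <- .read_scan(cfg)
    sel <- select_scales(res, plateau_eps = cfg$plateau_eps,
                         dip_quantile = cfg$dip_quantile,
                         min_plateau = cfg$min_plateau)
    utils::write.csv(data.frame(time = sel$time, n_comms = sel$n_comms,
                                plateau_len = sel$plateau_len),
                     .artifact(cfg, "selected.csv"), row.names = FALSE)
    write_memberships_csv(sel, .artifact(cfg, "memberships.csv"))
    .artifact(cfg, "selected.csv")
  })
}

.read_selected_memberships <- function(cfg) {
  df <- utils::read.csv(.require_artifact(cfg, "memberships.csv", "select"),
                        check.names = FALSE, colClasses = "character")
  ids <- df$id
  scales <- names(df)[-1]
  memb <- lapply(scales, function(s) as_partition(as.integer(df[[s]])))
  names(memb) <- scales
  list(ids = ids, memberships = memb)
}

#' Evaluate selected partitions
#'
#' Scores every selected scale: aggregate PMI topic coherence, and --
#' when reference categories are available -- NMI and hypergeometric
#' z-score contingency tables. Writes `scores.json`, per-scale
#' contingency CSVs, per-cluster n-gram summaries (`ngrams.json`) and
#' Sankey link exports (`sankey_<scale>.json`).
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the scores artifact path.
#' @export
pipeline_evaluate <- function(cfg) {
  .run_stage(cfg, "evaluate", function() {
    tk <- .read_tokens(.require_artifact(cfg, "tokens.jsonl", "preprocess"))
    sel <- .read_selected_memberships(cfg)
    toks <- tk$tokens[sel$ids]
    sumtoks <- tk$summary_tokens[sel$ids]
    stats <- word_stats(toks)
    labels <- NULL
    catp <- .artifact(cfg, "categories.csv")
    if (file.exists(catp)) {
      cd <- utils::read.csv(catp, colClasses = "character")
      labels <- stats::setNames(cd$category, cd$id)[sel$ids]
    }
    scores <- list()
    ngrams <- list()
    for (s in names(sel$memberships)) {
      memb <- sel$memberships[[s]]
      entry <- list(n_comms = max(memb),
                    aggregate_pmi = aggregate_pmi(memb, toks, stats = stats,
                                                  top_n = cfg$top_n_words))
      if (!is.null(labels)) {
        rep_ <- contingency_zscores(memb, labels)
        entry$nmi <- rep_$nmi
        utils::write.csv(rep_$counts,
                         .artifact(cfg, sprintf("contingency_%s.csv", s)))
        utils::write.csv(rep_$zscores,
                         .artifact(cfg, sprintf("zscores_%s.csv", s)))
        jsonlite::write_json(sankey_links(memb, labels),
                             .artifact(cfg, sprintf("sankey_%s.json", s)))
      }
      scores[[s]] <- entry
      ngrams[[s]] <- lapply(cluster_summaries(memb, sumtoks,
                                              n_top = cfg$n_top_ngrams),
                            function(v) as.list(v))
    }
    jsonlite::write_json(scores, .artifact(cfg, "scores.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(ngrams, .artifact(cfg, "ngrams.json"),
                         auto_unbox = TRUE)
    .artifact(cfg, "scores.json")
  })
}

#' Bundle the evaluation outputs into a single report
#'
#' Collects scores, selected scales and memberships into `report.json`.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the report path.
#' @export
pipeline_report <- function(cfg) {
  .run_stage(cfg, "report", function() {
    scores <- jsonlite::fromJSON(.require_artifact(cfg, "scores.json",
                                                   "evaluate"),
                                 simplifyVector = FALSE)
    selected <- utils::read.csv(.require_artifact(cfg, "selected.csv",
                                                  "select"))
    memb <- .read_selected_memberships(cfg)
    report <- list(config_hash = .config_hash(cfg),
                   master_seed = cfg$master_seed,
                   selected_scales = selected,
                   scores = scores,
                   memberships = c(list(id = memb$ids), memb$memberships))
    jsonlite::write_json(report, .artifact(cfg, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    .artifact(cfg, "report.json")
  })
}

#' Run the full analysis pipeline
#'
#' Executes the pipeline stages in order. With `synth = TRUE` a synthetic
#' corpus is generated first; otherwise the `corpus` config path is the
#' input. Stages are idempotent: rerunning with identical inputs and
#' configuration reproduces identical artifacts.
#'
#' @param cfg a [pipeline_config()].
#' @param steps character vector of stages to run, in order.
#' @return invisibly, the working directory.
#' @export
run_pipeline <- function(cfg, steps = c("preprocess", "embed", "graph",
                                        "scan", "select", "evaluate",
                                        "report")) {
  stage_fns <- list(synth = pipeline_synth, preprocess = pipeline_preprocess,
                    embed = pipeline_embed, graph = pipeline_graph,
                    scan = pipeline_scan, select = pipeline_select,
                    evaluate = pipeline_evaluate, report = pipeline_report)
  unknown <- setdiff(steps, names(stage_fns))
  if (length(unknown))
    stop("unknown pipeline step(s): ", paste(unknown, collapse = ", "))
  for (s in steps) stage_fns[[s]](cfg)
  invisible(cfg$workdir)
}
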
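# End-to-end orchestration: dock the generated set, filter, pick the
# top-scoring queries, retrieve analogs by GED, dock the analog pool, and
# compute the evaluation statistics (baseline resampling, pool-size curve,
# distance-score correlations). Deterministic under the mock engine and
# fixed seeds.

#' Pipeline configuration
#'
#' Defaults mirror the reference protocol: 10 queries selected from the
#' generated set, GED search radius 12 with up to 1000 raw hits, top 100
#' ranked hits per query, 5 conformers per molecule, ranking by Vina
#' efficiency.
#'
#' @param ... overrides of any field.
#' @return config list.
#' @export
mgvs_config <- function(...) {
  cfg <- list(top_queries = 10L, max_ged = 12L, max_raw_hits = 1000L,
              top_hits_per_query = 100L, conformers_per_mol = 5L,
              ranking = "vina_eff", seed = 1L, want_poses = FALSE,
              filter = default_filter_config(), cutoffs = default_cutoffs(),
              out_dir = NULL)
  over <- list(...)
  for (k in names(over)) cfg[[k]] <- over[[k]]
  stopifnot(cfg$top_queries >= 1, cfg$top_hits_per_query >= 1,
            cfg$top_hits_per_query <= cfg$max_raw_hits,
            cfg$ranking %in% c("vina_eff", "vina"))
  cfg
}

# Dock a molecule set. The mock engine scores molecular identity directly
# (no 3D needed); any other engine, or want_poses, runs the full conformer
# -> cluster -> relax -> score chain and keeps the best conformer.
dock_set <- function(mols, rec, engine, config) {
  need_pose <- config$want_poses || engine$tag != "mock"
  out <- vector("list", length(mols))
  for (i in seq_along(mols)) {
    m <- mols[[i]]
    out[[i]] <- tryCatch({
      if (!need_pose) {
        v <- engine$score(m, NULL, rec)
        structure(list(id = m$id, conformer = 1L, pose = NULL, vina = v,
                       vina_eff = vina_efficiency(v, n_heavy_atoms(m)),
                       engine = engine$tag), class = "mgvs_docking_result")
      } else {
        cs <- generate_conformers(m, n = config$conformers_per_mol,
                                  seed = config$seed)
        cs <- relax(cluster_conformers(cs))
        best_result(score_pose(cs, rec, engine))
      }
    }, mgvs_error = function(e) {
      warning(sprintf("docking failed for '%s': %s", m$id,
                      conditionMessage(e)))
      NULL
    })
  }
  names(out) <- vapply(mols, `[[`, "", "id")
  out
}

#' Select query compounds from a scored generated set
#'
#' Applies the compound filter stack, then sorts the survivors by the
#' configured metric (Vina efficiency by default, ascending = best first;
#' ties by raw score, then id) and returns the best `k`.
#'
#' @param scored list of entries `list(mol = <mgvs_mol>, result =
#'   <mgvs_docking_result>)`.
#' @param filter_config filter configuration.
#' @param k number of queries (default 10).
#' @param ranking `"vina_eff"` or `"vina"`.
#' @return list of selected entries (possibly fewer than `k`, with a
#'   warning).
#' @export
select_queries <- function(scored, filter_config = default_filter_config(),
                           k = 10L, ranking = "vina_eff") {
  if (!length(scored)) {
    abort_mgvs("empty scored set", "mgvs_argument_error")
  }
  mols <- lapply(scored, `[[`, "mol")
  flt <- apply_filter_stack(mols, filter_config)
  surviving_ids <- vapply(flt$survivors, `[[`, "", "id")
  kept <- scored[vapply(scored, function(e) e$mol$id %in% surviving_ids, TRUE)]
  if (!length(kept)) {
    warning("all molecules removed by the filter stack")
    return(list())
  }
  metric <- vapply(kept, function(e) e$result[[ranking]], 1.0)
  raw <- vapply(kept, function(e) e$result$vina, 1.0)
  ids <- vapply(kept, function(e) e$mol$id, "")
  kept <- kept[order(metric, raw, ids)]
  if (length(kept) < k) {
    warning(sprintf("only %d of %d requested queries survive filtering",
                    length(kept), k))
  }
  utils::head(kept, k)
}

#' Rank raw search hits and truncate
#'
#' Orders by (GED, Daylight-style path distance, hit id) and keeps the
#' first `top_k`.
#'
#' @param raw_hits hit data.frame from [query_index()].
#' @param top_k hits to keep (default 100).
#' @return ranked, truncated data.frame.
#' @export
rank_hits <- function(raw_hits, top_k = 100L) {
  if (!nrow(raw_hits)) return(raw_hits)
  o <- order(raw_hits$ged, raw_hits$daylight_dist, raw_hits$hit_id)
  utils::head(raw_hits[o, , drop = FALSE], top_k)
}

#' Run the model-guided virtual screening pipeline
#'
#' Executes dock -> filter -> query selection -> GED analog retrieval ->
#' hit ranking -> hit docking -> best-analog selection, and assembles the
#' evaluation table. Fully deterministic under the mock engine and fixed
#' seeds.
#'
#' @param generated list of `mgvs_mol` (the candidate set to screen).
#' @param library list of `mgvs_mol` or a prebuilt `mgvs_ged_index`.
#' @param receptor `mgvs_receptor`.
#' @param engine engine adapter (default: mock engine seeded from config).
#' @param config [mgvs_config()].
#' @return `mgvs_eval`: list with `queries`, `hits`, `best_analogs`
#'   (data.frames), `correlations`, `config` echoes and, when
#'   `config$out_dir` is set, the paths of the written artifacts.
#' @export
run_mgvs <- function(generated, library, receptor, engine = NULL,
                     config = mgvs_config()) {
  if (is.null(engine)) engine <- mock_engine(config$seed)
  index <- if (inherits(library, "mgvs_ged_index")) library else
    build_index(library)
  gen_results <- dock_set(generated, receptor, engine, config)
  scored <- list()
  for (i in seq_along(generated)) {
    if (!is.null(gen_results[[i]])) {
      scored[[length(scored) + 1L]] <- list(mol = generated[[i]],
                                            result = gen_results[[i]])
    }
  }
  queries <- select_queries(scored, config$filter, config$top_queries,
                            config$ranking)
  qdf <- do.call(rbind, lapply(queries, function(q) data.frame(
    query_id = q$mol$id, smiles = q$mol$smiles, vina = q$result$vina,
    heavy_atoms = n_heavy_atoms(q$mol), vina_eff = q$result$vina_eff,
    stringsAsFactors = FALSE)))
  hit_rows <- list()
  best_rows <- list()
  hit_score_cache <- new.env(parent = emptyenv())
  for (q in queries) {
    raw <- query_index(index, q$mol, max_ged = config$max_ged,
                       max_hits = config$max_raw_hits)
    ranked <- rank_hits(raw, config$top_hits_per_query)
    if (!nrow(ranked)) next
    for (j in seq_len(nrow(ranked))) {
      hm <- index$mols[[ranked$hit_id[j]]]
      ck <- hm$smiles
      res <- hit_score_cache[[ck]]
      if (is.null(res)) {
        res <- dock_set(list(hm), receptor, engine, config)[[1]]
        if (!is.null(res)) hit_score_cache[[ck]] <- res
      }
      if (is.null(res)) next
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        query_id = q$mol$id, hit_id = hm$id, ged = ranked$ged[j],
        daylight_dist = ranked$daylight_dist[j],
        ecfp4_dist = ranked$ecfp4_dist[j], vina = res$vina,
        heavy_atoms = n_heavy_atoms(hm), vina_eff = res$vina_eff,
        delta_vina = delta_vina(res$vina, q$result$vina),
        stringsAsFactors = FALSE)
    }
    qh <- do.call(rbind, hit_rows)
    qh <- qh[qh$query_id == q$mol$id, , drop = FALSE]
    if (nrow(qh)) {
      b <- qh[order(qh$vina, qh$hit_id), , drop = FALSE][1, ]
      best_rows[[length(best_rows) + 1L]] <- b
    }
  }
  hdf <- do.call(rbind, hit_rows) %||% data.frame()
  bdf <- do.call(rbind, best_rows) %||% data.frame()
  rownames(hdf) <- NULL
  rownames(bdf) <- NULL
  cors <- if (!is.null(hdf$delta_vina) && nrow(hdf) >= 3) {
    distance_score_correlation(hdf)
  } else {
    list(ged = NA_real_, daylight_dist = NA_real_, ecfp4_dist = NA_real_)
  }
  eval_tab <- structure(list(
    queries = qdf %||% data.frame(), hits = hdf, best_analogs = bdf,
    correlations = cors,
    meta = list(n_generated = length(generated),
                library_size = index$meta$size, engine = engine$tag,
                seed = config$seed)), class = "mgvs_eval")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_artifact(eval_tab$queries, file.path(config$out_dir, "queries.tsv"))
    write_tsv_artifact(eval_tab$hits, file.path(config$out_dir, "hits.tsv"))
    write_tsv_artifact(eval_tab$best_analogs,
                       file.path(config$out_dir, "best_analogs.tsv"))
    json <- jsonlite::toJSON(list(
      correlations = lapply(cors, function(x) round(x, 10)),
      meta = eval_tab$meta,
      n_queries = nrow(eval_tab$queries),
      n_hits = nrow(eval_tab$hits),
      median_query_vina_eff = stats::median(eval_tab$queries$vina_eff),
      median_best_delta_vina = if (nrow(bdf)) stats::median(bdf$delta_vina)
      else NA_real_),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    writeLines(json, file.path(config$out_dir, "eval.json"))
  }
  eval_tab
}

#' @export
print.mgvs_eval <- function(x, ...) {
  cat(sprintf("<mgvs evaluation: %d queries, %d docked hits, %d best analogs>\n",
              nrow(x$queries), nrow(x$hits), nrow(x$best_analogs)))
  if (nrow(x$best_analogs)) {
    cat(sprintf("  median best-analog delta-Vina: %.3f kcal/mol\n",
                stats::median(x$best_analogs$delta_vina)))
  }
  invisible(x)
}

#' Welch's unequal-variance t statistic
#'
#' Two-sided two-sample t-test without the equal-variance assumption
#' (Welch-Satterthwaite degrees of freedom), as used by the baseline
#' comparison.
#'
#' @param x,y numeric samples.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  res <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Compare screening results against random-subset baselines
#'
#' For each requested subset size, draws `n_repeats` random subsets of the
#' scored pool, records the median of the 10 best Vina-efficiency values
#' per draw, and reports mean and standard deviation across draws together
#' with a two-sided Welch (unequal-variance) t-test against the query and
#' hit top-10 distributions.
#'
#' @param query_scores,hit_scores numeric vectors (top-10 Vina efficiencies).
#' @param random_pool numeric vector of pool Vina efficiencies.
#' @param subset_sizes integer vector; each must be <= pool size.
#' @param n_repeats draws per size (default 20).
#' @param seed integer seed.
#' @return data.frame: `subset_size`, `mean_median_top10`, `sd_median_top10`,
#'   `welch_t_query`, `welch_p_query`, `welch_t_hits`, `welch_p_hits`.
#' @export
baseline_compare <- function(query_scores, hit_scores, random_pool,
                             subset_sizes, n_repeats = 20L, seed = 1L) {
  if (any(subset_sizes > length(random_pool))) {
    abort_mgvs("subset size exceeds pool size", "mgvs_argument_error")
  }
  median_top10 <- function(x) stats::median(utils::head(sort(x), 10))
  rows <- list()
  with_seed(derive_seed(seed, "baseline"), {
    for (s in subset_sizes) {
      vals <- vapply(seq_len(n_repeats), function(r) {
        median_top10(sample(random_pool, s))
      }, 1.0)
      wt <- function(ref) {
        res <- tryCatch(welch_t(ref, vals), error = function(e) NULL)
        if (is.null(res)) c(NA_real_, NA_real_) else c(res$t, res$p)
      }
      wq <- wt(query_scores)
      wh <- wt(hit_scores)
      rows[[length(rows) + 1L]] <- data.frame(
        subset_size = s, mean_median_top10 = mean(vals),
        sd_median_top10 = stats::sd(vals),
        welch_t_query = wq[1], welch_p_query = wq[2],
        welch_t_hits = wh[1], welch_p_hits = wh[2])
    }
  })
  do.call(rbind, rows)
}

#' Average best-analog improvement as a function of docked pool size
#'
#' For each pool size `s`, each query contributes the best (minimum) Vina
#' score among its first `s` ranked hits minus its own score; the curve is
#' the across-query mean with a normal-approximation confidence interval.
#' Non-increasing in `s` by construction.
#'
#' @param per_query list of entries `list(query_vina = <num>, hit_vinas =
#'   <numeric vector in ranked order>)`.
#' @param pool_sizes integer vector (default 1:100).
#' @param confidence CI level (default 0.95).
#' @return data.frame: `pool_size`, `mean_delta`, `ci_lo`, `ci_hi`,
#'   `n_queries`, `truncated` (TRUE when some query had fewer hits than
#'   `pool_size`).
#' @export
pool_size_curve <- function(per_query, pool_sizes = 1:100,
                            confidence = 0.95) {
  stopifnot(length(per_query) >= 1)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  rows <- lapply(pool_sizes, function(s) {
    deltas <- vapply(per_query, function(q) {
      use <- utils::head(q$hit_vinas, s)
      min(use) - q$query_vina
    }, 1.0)
    trunc <- any(vapply(per_query, function(q) length(q$hit_vinas) < s, TRUE))
    se <- if (length(deltas) > 1) stats::sd(deltas) / sqrt(length(deltas)) else 0
    data.frame(pool_size = s, mean_delta = mean(deltas),
               ci_lo = mean(deltas) - z * se, ci_hi = mean(deltas) + z * se,
               n_queries = length(deltas), truncated = trunc)
  })
  do.call(rbind, rows)
}

#' Spearman correlation of score change with chemical distances
#'
#' Rank correlation (average ranks for ties) of per-hit `delta_vina`
#' against GED and both fingerprint distances. Constant inputs yield `NA`
#' with a warning.
#'
#' @param hits data.frame with `delta_vina`, `ged`, `daylight_dist`,
#'   `ecfp4_dist` (>= 3 rows).
#' @return list of correlations: `ged`, `daylight_dist`, `ecfp4_dist`.
#' @export
distance_score_correlation <- function(hits) {
  if (nrow(hits) < 3) {
    abort_mgvs("need at least 3 hit records for correlation",
               "mgvs_argument_error")
  }
  one <- function(v) {
    if (stats::sd(v) == 0 || stats::sd(hits$delta_vina) == 0) {
      warning("constant input: Spearman correlation undefined")
      return(NA_real_)
    }
    stats::cor(hits$delta_vina, v, method = "spearman")
  }
  list(ged = one(hits$ged), daylight_dist = one(hits$daylight_dist),
       ecfp4_dist = one(hits$ecfp4_dist))
}
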
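# End-to-end driver-induced modular screening: simulate or load the four
# groups, detect modules per treatment, classify On/conserved modules and
# the combination's synergy modules, screen DEGs, measure target-set
# separation on the interaction network, rank drivers, and run a local
# enrichment — all from one seeded configuration, with every artifact
# written as TSV/JSON plus a checksummed manifest.

#' Configuration of a full screening run
#'
#' Either `simulation` (a [sim_config()]; the run generates its own data)
#' or `inputs` (paths to an expression TSV, a sample-to-group map TSV and
#' an edge-list TSV) must be given. Group roles are named explicitly and
#' never inferred from file names.
#'
#' @param simulation Optional [sim_config()] object.
#' @param inputs Optional list with paths `expr`, `group_map`, `network`.
#' @param roles Named list mapping the roles `sham`, `drugA`, `drugB`,
#'   `combo` to group labels in the data.
#' @param beta `"auto"` (scale-free criterion per group) or a named numeric
#'   vector of per-group powers (explicit overrides, e.g. published
#'   values, bypass selection).
#' @param min_size Minimum module size.
#' @param n_perm,seed Preservation permutation count and master seed.
#' @param fc_min,p_max,use_bonferroni DEG screen thresholds.
#' @param k,fc_column Driver ranking parameters.
#' @param annotation Optional GMT path or named list of term gene sets; in
#'   simulation mode a synthetic annotation is built from the planted
#'   modules when omitted.
#' @return A validated `dims_run_config` list.
#' @export
run_config <- function(simulation = NULL, inputs = NULL,
                       roles = list(sham = "sham", drugA = "drugA",
                                    drugB = "drugB", combo = "combo"),
                       beta = "auto", min_size = 3L, n_perm = 200L,
                       seed = 1L, fc_min = 1.2, p_max = 0.05,
                       use_bonferroni = FALSE, k = 10L,
                       fc_column = c("raw", "norm"), annotation = NULL) {
  fc_column <- match.arg(fc_column)
  if (is.null(simulation) == is.null(inputs)) {
    abort("Provide exactly one of `simulation` or `inputs`.")
  }
  if (!is.null(inputs)) {
    needed <- c("expr", "group_map", "network")
    if (!all(needed %in% names(inputs))) {
      abort("`inputs` must name paths expr, group_map and network.")
    }
    missing <- unlist(inputs[needed])[!file.exists(unlist(inputs[needed]))]
    if (length(missing)) {
      abort(sprintf("Input file(s) not found: %s", paste(missing, collapse = ", ")))
    }
  }
  if (!all(c("sham", "drugA", "drugB", "combo") %in% names(roles))) {
    abort("`roles` must name sham, drugA, drugB and combo.")
  }
  structure(list(simulation = simulation, inputs = inputs, roles = roles,
                 beta = beta, min_size = as.integer(min_size),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 fc_min = fc_min, p_max = p_max,
                 use_bonferroni = use_bonferroni, k = as.integer(k),
                 fc_column = fc_column, annotation = annotation),
            class = "dims_run_config")
}

#' Run the full driver-induced modular screen
#'
#' Executes, in order: (1) simulate or load the data; (2) module detection
#' per treated group; (3) preservation/classification of every treated
#' group's modules against sham, of the combination against each single
#' drug, and the synergy-module call; (4) DEG screening per treated group
#' plus overlap summaries; (5) target-set separation on the interaction
#' network (DEG level and On-module level); (6) driver ranking between the
#' single-drug On-module gene sets; (7) over-representation of the synergy
#' module genes. Every stage writes plain TSV/JSON artifacts into
#' `out_dir`; a manifest with md5 checksums, seeds and wall times is
#' written last. Re-running with the same config reproduces identical
#' non-timing outputs.
#'
#' @param config A [run_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (`dims_manifest` list).
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(simulation = synergy_config(seed = 1), n_perm = 100)
#' man <- run_pipeline(cfg, tempfile("dims-run-"))
#' man$stages$sy$sy_modules
#' }
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "dims_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stages = list(), files = character())
  t_total <- proc.time()[["elapsed"]]

  emit <- function(stage, outputs, extra = list()) {
    manifest$stages[[stage]] <<- c(list(outputs = outputs), extra)
    manifest$files <<- unique(c(manifest$files, outputs))
  }
  out_path <- function(...) file.path(out_dir, paste0(...))
  run_stage <- function(stage, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
    })
    manifest$stages[[stage]]$wall_time <<- proc.time()[["elapsed"]] - t0
    res
  }

  roles <- config$roles
  treated <- c("drugA", "drugB", "combo")

  ## stage 1: data -----------------------------------------------------
  dat <- run_stage("data", function() {
    if (!is.null(config$simulation)) {
      sim <- simulate_expression(config$simulation)
      net <- simulate_network(config$simulation)
      truth <- sim$truth
      truth$target_a <- net$truth$target_a
      truth$target_b <- net$truth$target_b
      truth$bridges <- net$truth$bridges
      files <- character()
      for (g in names(sim$expr)) {
        f <- out_path("expr_", g, ".tsv")
        write_expression(sim$expr[[g]], f)
        files <- c(files, f)
      }
      write_group_map(sim$group_map, out_path("group_map.tsv"))
      write_edge_list(igraph::as_data_frame(net$graph, what = "edges"),
                      out_path("network_edges.tsv"))
      write_ground_truth(truth, out_path("ground_truth.json"))
      emit("data", basename(c(files, out_path("group_map.tsv"),
                              out_path("network_edges.tsv"),
                              out_path("ground_truth.json"))),
           list(mode = "simulated", seed = config$simulation$seed))
      list(expr = sim$expr, graph = net$graph, truth = truth)
    } else {
      m <- read_expression(config$inputs$expr)
      gm <- read_group_map(config$inputs$group_map)
      expr <- lapply(setNames(nm = unlist(roles)), function(g) {
        m[, gm$sample[gm$group == g], drop = FALSE]
      })
      names(expr) <- names(roles)[match(names(expr), unlist(roles))]
      graph <- interaction_network(config$inputs$network)
      emit("data", character(), list(mode = "loaded"))
      list(expr = expr[c("sham", treated)], graph = graph, truth = NULL)
    }
  })
  expr <- dat$expr

  ## stage 2: modules per treated group --------------------------------
  modules <- run_stage("modules", function() {
    out <- list()
    files <- character()
    for (g in treated) {
      beta_g <- if (identical(config$beta, "auto")) {
        sft <- pick_soft_threshold(expr[[g]])
        f <- out_path("sft_", g, ".tsv")
        readr::write_tsv(tibble::as_tibble(sft), f)
        files <- c(files, f)
        attr(sft, "chosen_beta")
      } else {
        config$beta[[g]]
      }
      net <- build_network(expr[[g]], beta = beta_g)
      mods <- detect_modules(net, min_size = config$min_size)
      f <- out_path("modules_", g, ".tsv")
      readr::write_tsv(tibble::as_tibble(mods), f)
      files <- c(files, f)
      out[[g]] <- list(beta = beta_g, net = net, modules = mods)
    }
    emit("modules", basename(files),
         list(beta = lapply(out, `[[`, "beta")))
    out
  })

  ## stage 3: preservation, On/conserved classes, Sy modules -----------
  pres <- run_stage("preservation", function() {
    comparisons <- list(
      drugA_vs_sham = c("drugA", "sham"),
      drugB_vs_sham = c("drugB", "sham"),
      combo_vs_sham = c("combo", "sham"),
      combo_vs_drugA = c("combo", "drugA"),
      combo_vs_drugB = c("combo", "drugB"))
    out <- list()
    files <- character()
    for (nm in names(comparisons)) {
      cmp <- comparisons[[nm]]
      p <- module_preservation(expr[[cmp[1]]], expr[[cmp[2]]],
                               modules[[cmp[1]]]$modules,
                               beta = modules[[cmp[1]]]$beta,
                               n_perm = config$n_perm,
                               seed = derive_seed(config$seed, nm))
      f <- out_path("preservation_", nm, ".tsv")
      readr::write_tsv(tibble::as_tibble(p), f)
      files <- c(files, f)
      out[[nm]] <- p
    }
    emit("preservation", basename(files), list(n_perm = config$n_perm))
    out
  })

  sy <- run_stage("sy", function() {
    rep <- identify_sy_modules(pres$combo_vs_sham, pres$combo_vs_drugA,
                               pres$combo_vs_drugB)
    f <- out_path("sy_report.json")
    jsonlite::write_json(list(
      sy_modules = rep$sy_modules,
      on_vs_sham = rep$on_vs_sham,
      on_vs_drugA = rep$on_vs_drugA,
      on_vs_drugB = rep$on_vs_drugB,
      provenance = as.data.frame(rep$provenance)
    ), f, pretty = TRUE)
    emit("sy", basename(f), list(sy_modules = rep$sy_modules))
    rep
  })

  ## stage 4: DEGs -----------------------------------------------------
  degs <- run_stage("degs", function() {
    out <- list()
    files <- character()
    for (g in treated) {
      d <- differential_expression(expr$sham, expr[[g]])
      f <- out_path("degs_", g, ".tsv")
      readr::write_tsv(tibble::as_tibble(d), f)
      files <- c(files, f)
      out[[g]] <- d
    }
    sets <- lapply(out, filter_degs, fc_min = config$fc_min,
                   p_max = config$p_max,
                   use_bonferroni = config$use_bonferroni)
    ov <- overlap_analysis(sets)
    f <- out_path("deg_overlap.tsv")
    readr::write_tsv(ov, f)
    emit("degs", basename(c(files, f)),
         list(n_degs = lapply(sets, length)))
    list(tables = out, sets = sets)
  })

  ## stage 5: separation on the interaction network --------------------
  seps <- run_stage("separation", function() {
    on_genes <- function(g) {
      ids <- on_modules(pres[[paste0(g, "_vs_sham")]])
      unique(unlist(lapply(ids, module_genes, modules = modules[[g]]$modules)))
    }
    set_list <- list(
      degs_drugA = degs$sets$drugA, degs_drugB = degs$sets$drugB,
      degs_combo = degs$sets$combo,
      on_drugA = on_genes("drugA"), on_drugB = on_genes("drugB"))
    pairs <- list(c("degs_drugA", "degs_drugB"),
                  c("degs_drugA", "degs_combo"),
                  c("degs_drugB", "degs_combo"),
                  c("on_drugA", "on_drugB"))
    rows <- purrr::map_dfr(pairs, function(p) {
      res <- tryCatch(
        suppressWarnings(separation(dat$graph, set_list[[p[1]]],
                                    set_list[[p[2]]])),
        error = function(e) NULL)
      if (is.null(res)) {
        return(tibble::tibble(set_a = p[1], set_b = p[2], d_ab = NA_real_,
                              d_aa = NA_real_, d_bb = NA_real_,
                              s_ab = NA_real_, n_mapped_a = NA_integer_,
                              n_mapped_b = NA_integer_,
                              n_dropped = NA_integer_))
      }
      bind_cols(tibble::tibble(set_a = p[1], set_b = p[2]),
                tibble::as_tibble(res))
    })
    f <- out_path("separation.tsv")
    readr::write_tsv(rows, f)
    emit("separation", basename(f))
    list(table = rows, sets = set_list)
  })

  ## stage 6: driver ranking -------------------------------------------
  drivers <- run_stage("drivers", function() {
    a <- seps$sets$on_drugA
    b <- seps$sets$on_drugB
    rk <- suppressWarnings(
      rank_drivers(dat$graph, a, b, k = config$k, fc_column = config$fc_column))
    f <- out_path("drivers.tsv")
    readr::write_tsv(tibble::as_tibble(rk), f)
    emit("drivers", basename(f),
         list(drivers = attr(rk, "drivers"), common = attr(rk, "common")))
    rk
  })

  ## stage 7: enrichment of the synergy-module genes -------------------
  enrich <- run_stage("enrichment", function() {
    anno <- config$annotation
    if (is.character(anno) && length(anno) == 1L) anno <- read_gmt(anno)
    background <- rownames(expr$sham)
    if (is.null(anno)) {
      if (is.null(dat$truth)) {
        emit("enrichment", character(), list(skipped = "no annotation supplied"))
        return(NULL)
      }
      # synthetic annotation from the planted modules plus seeded random
      # terms, so the stage is exercised without external databases
      anno <- synthetic_annotation(dat$truth, background,
                                   seed = derive_seed(config$seed, "annotation"))
    }
    query <- unique(unlist(lapply(sy$sy_modules, module_genes,
                                  modules = modules$combo$modules)))
    if (!length(query)) {
      emit("enrichment", character(), list(skipped = "no synergy-module genes"))
      return(NULL)
    }
    res <- overrepresentation(query, anno, background = background)
    f <- out_path("enrichment.tsv")
    readr::write_tsv(tibble::as_tibble(res), f)
    emit("enrichment", basename(f))
    res
  })

  ## manifest ----------------------------------------------------------
  paths <- file.path(out_dir, manifest$files)
  manifest$checksums <- as.list(setNames(unname(tools::md5sum(paths)),
                                         manifest$files))
  manifest$seed <- config$seed
  manifest$wall_time_total <- proc.time()[["elapsed"]] - t_total
  manifest$config <- serialize_config(config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  manifest <- structure(manifest, class = "dims_manifest")
  invisible(manifest)
}

# Synthetic GMT-style annotation: one term per planted module plus random
# terms drawn from the background (clearly synthetic; for exercising the
# enrichment stage only).
synthetic_annotation <- function(truth, background, seed, n_random = 10L) {
  set.seed(seed)
  anno <- list()
  for (m in sort(unique(truth$modules$module[truth$modules$module > 0]))) {
    anno[[sprintf("synthetic_module_%d", m)]] <-
      truth$modules$gene[truth$modules$module == m]
  }
  for (i in seq_len(n_random)) {
    anno[[sprintf("synthetic_random_%02d", i)]] <-
      sample(background, min(30L, length(background)))
  }
  anno
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$simulation)) {
    cfg$simulation <- lapply(unclass(cfg$simulation), function(x) {
      if (is.data.frame(x)) as.list(x) else x
    })
  }
  cfg
}

#' @export
print.dims_manifest <- function(x, ...) {
  cat("<dims_manifest>\n")
  cat(sprintf("  stages: %s\n", paste(names(x$stages), collapse = ", ")))
  cat(sprintf("  files: %d, total wall time %.1fs\n",
              length(x$files), x$wall_time_total))
  invisible(x)
}

#' Verify the checksums recorded in a run manifest
#'
#' @param out_dir Directory containing `manifest.json` and the artifacts.
#' @return TRUE invisibly if all checksums match; errors otherwise.
#' @export
verify_manifest <- function(out_dir) {
  man <- jsonlite::read_json(file.path(out_dir, "manifest.json"),
                             simplifyVector = TRUE)
  current <- tools::md5sum(file.path(out_dir, names(man$checksums)))
  stored <- unlist(man$checksums)
  bad <- names(stored)[unname(current) != unname(stored)]
  if (length(bad)) {
    abort(sprintf("Checksum mismatch for: %s", paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}
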
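default_config <- function() {
  list(
    stages = "mr",
    p_thresh = 0.05, pleio_thresh = 0.05,
    p_smr_thresh = 0.05, p_heidi_thresh = 0.05,
    smr_cohort_rule = "any",
    k = 6L, B = 10000L, quantile = 0.75,
    lfc_min = 0.5, fdr_max = 0.05,
    marker_gene = "PGAP3",
    panel = c("CXCL14", "TNFSF13B", "TNFSF18"),
    seed = NA_integer_,
    discovery = NULL, replication = NULL, smr = NULL,
    spots = NULL, marker_signal = "marker", immune_signal = "immune",
    mtx = NULL, genes = NULL, cells = NULL, bulk = NULL,
    out = NULL
  )
}

#' Parse a flat key: value config file
#'
#' One \code{key: value} pair per line; blank lines and \code{#} comments
#' ignored. Comma-separated values become vectors; numeric-looking values are
#' converted. Unknown keys are rejected.
#'
#' @param path Config file path.
#' @return Named list merged over the package defaults.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- default_config()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE)) stop("config: malformed line: ", ln)
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    if (!key %in% names(cfg)) stop("config: unknown key: ", key)
    if (grepl(",", val, fixed = TRUE)) val <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    if (all(!is.na(num))) val <- num
    cfg[[key]] <- val
  }
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("config: ", msg, call. = FALSE)
  in01 <- function(x) is.numeric(x) && length(x) == 1L && x > 0 && x < 1
  for (f in c("p_thresh", "pleio_thresh", "p_smr_thresh", "p_heidi_thresh",
              "quantile", "fdr_max"))
    chk(in01(cfg[[f]]), paste(f, "must be a single value in (0, 1)"))
  chk(cfg$smr_cohort_rule %in% c("any", "all"),
      "smr_cohort_rule must be 'any' or 'all'")
  chk(cfg$k >= 1, "k must be >= 1")
  chk(cfg$B >= 1, "B must be >= 1")
  chk(cfg$lfc_min >= 0, "lfc_min must be >= 0")
  stochastic <- any(c("simulate", "spatial") %in% cfg$stages)
  chk(!stochastic || !is.na(cfg$seed),
      "seed is mandatory for stochastic stages")
  invisible(cfg)
}

#' Validate pipeline input files against their schemas
#'
#' Per-file checks of required columns, types and value ranges with row-level
#' messages (standard errors must be positive, p-values in (0, 1], spot
#' coordinates unique, counts non-negative integers).
#'
#' @param paths Named character vector or list; recognized names:
#'   \code{discovery}, \code{replication} (TMR metric tables), \code{smr},
#'   \code{summary_stats}, \code{spots}, \code{bulk}.
#' @return data.frame \code{file, problem} of diagnostics; zero rows when all
#'   inputs validate.
#' @export
validate_inputs <- function(paths) {
  diags <- list()
  note <- function(file, problem)
    diags[[length(diags) + 1L]] <<- data.frame(file = file, problem = problem,
                                               stringsAsFactors = FALSE)
  check_p <- function(file, p, col) {
    bad <- which(!is.na(p) & (p <= 0 | p > 1))
    if (length(bad) > 0L)
      note(file, paste0(col, " outside (0,1] at row(s) ",
                        paste(utils::head(bad, 5L), collapse = ", ")))
  }
  for (nm in names(paths)) {
    path <- paths[[nm]]
    if (is.null(path)) next
    if (!file.exists(path)) {
      note(path, "file does not exist")
      next
    }
    res <- tryCatch({
      if (nm %in% c("discovery", "replication")) {
        d <- read_gene_metrics(path)
        check_p(path, d$pval, "pval")
        check_p(path, d$pleiotropy_pval, "pleiotropy_pval")
        bad <- which(d$or <= 0)
        if (length(bad) > 0L)
          note(path, paste0("or <= 0 at row(s) ",
                            paste(utils::head(bad, 5L), collapse = ", ")))
      } else if (nm == "smr") {
        d <- read_smr_metrics(path)
        check_p(path, d$p_smr, "p_smr")
        check_p(path, d$p_heidi, "p_heidi")
      } else if (nm == "summary_stats") {
        d <- read_summary_stats(path)
        bad <- which(d$se <= 0)
        if (length(bad) > 0L)
          note(path, paste0("se <= 0 at row(s) ",
                            paste(utils::head(bad, 5L), collapse = ", ")))
        check_p(path, d$pval, "pval")
      } else if (nm == "spots") {
        header <- readLines(path, n = 1L)
        sep <- if (grepl("\t", header)) "\t" else ","
        d <- utils::read.table(path, sep = sep, header = TRUE)
        miss <- setdiff(c("spot_id", "x", "y"), names(d))
        if (length(miss) > 0L)
          note(path, paste("missing columns:", paste(miss, collapse = ", ")))
        else if (anyDuplicated(d[, c("x", "y")]))
          note(path, paste0("duplicate spot coordinates at row(s) ",
                            paste(utils::head(which(duplicated(d[, c("x", "y")])),
                                              5L), collapse = ", ")))
      } else if (nm == "bulk") {
        read_bulk_expression(path)
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) note(path, res)
  }
  if (length(diags) == 0L)
    data.frame(file = character(0), problem = character(0),
               stringsAsFactors = FALSE)
  else do.call(rbind, diags)
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stages in order - \code{simulate} (write synthetic
#' inputs), \code{mr} (two-stage TMR filter + SMR/HEIDI intersection +
#' direction classification), \code{spatial} (immune-exclusion permutation
#' tests), \code{strata} (marker screen on counts and/or immune-factor panel
#' on bulk) - writing each stage's outputs under \code{config$out} and a
#' machine-readable \code{report.json} recording settings, headline numbers
#' and the seed. Deterministic given the seed.
#'
#' @param config Named list (see \code{\link{read_config}}) or a config file
#'   path. Unset fields take the package defaults.
#' @return The run report, invisibly (also written to
#'   \code{out/report.json}).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  cfg <- utils::modifyList(default_config(), config, keep.null = TRUE)
  validate_config(cfg)
  if (is.null(cfg$out)) stop("config: 'out' directory is required")
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.na(cfg$seed)) NULL else as.integer(cfg$seed)
  report <- list(settings = cfg[c("stages", "p_thresh", "pleio_thresh",
                                  "p_smr_thresh", "p_heidi_thresh",
                                  "smr_cohort_rule", "k", "B", "quantile",
                                  "lfc_min", "fdr_max", "seed")],
                 stages = list())
  write_report <- function() {
    jsonlite::write_json(report, file.path(cfg$out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", na = "null")
  }

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      report$stages[[name]] <<- list(error = conditionMessage(e))
      write_report()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    report$stages[[name]] <<- res
  }

  if ("simulate" %in% cfg$stages) run_stage("simulate", function() {
    mr <- simulate_mr_dataset(seed = seed)
    write_summary_stats(mr$exposure, file.path(cfg$out, "exposure.tsv"))
    write_summary_stats(mr$outcome, file.path(cfg$out, "outcome.tsv"))
    grid <- simulate_spot_grid(pattern = "exclusion", seed = seed + 1L)
    write_spot_table(grid, file.path(cfg$out, "spots.tsv"))
    m <- simulate_counts(seed = seed + 2L)
    write_cell_matrix(m, file.path(cfg$out, "counts.mtx"),
                      file.path(cfg$out, "genes.txt"),
                      file.path(cfg$out, "cells.txt"))
    bulk <- simulate_bulk(marker_gene = cfg$marker_gene, seed = seed + 3L)
    write_bulk_expression(bulk, file.path(cfg$out, "bulk.tsv"))
    cfg$spots <<- file.path(cfg$out, "spots.tsv")
    cfg$mtx <<- file.path(cfg$out, "counts.mtx")
    cfg$genes <<- file.path(cfg$out, "genes.txt")
    cfg$cells <<- file.path(cfg$out, "cells.txt")
    cfg$bulk <<- file.path(cfg$out, "bulk.tsv")
    list(seed = seed, files = c("exposure.tsv", "outcome.tsv", "spots.tsv",
                                "counts.mtx", "genes.txt", "cells.txt",
                                "bulk.tsv"))
  })

  if ("mr" %in% cfg$stages) run_stage("mr", function() {
    if (is.null(cfg$discovery) || is.null(cfg$replication) || is.null(cfg$smr))
      stop("mr stage needs 'discovery', 'replication' and 'smr' tables")
    diag <- validate_inputs(list(discovery = cfg$discovery,
                                 replication = cfg$replication, smr = cfg$smr))
    if (nrow(diag) > 0L)
      stop(paste(diag$file, diag$problem, sep = ": ", collapse = "; "))
    tmr <- read_gene_metrics(cfg$discovery)
    repl <- read_gene_metrics(cfg$replication)
    smr <- read_smr_metrics(cfg$smr)
    supported <- two_stage_filter(tmr, repl, cfg$p_thresh, cfg$pleio_thresh)
    cand <- prioritize_candidates(supported, rbind(tmr, repl), smr,
                                  cfg$p_smr_thresh, cfg$p_heidi_thresh,
                                  cfg$smr_cohort_rule)
    utils::write.table(cand, file.path(cfg$out, "candidates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    dirs <- cand$direction[cand$retained]
    list(n_discovery = nrow(tmr), n_tmr_supported = length(supported),
         n_retained = sum(cand$retained),
         n_risk_increasing = sum(dirs == "risk_increasing"),
         n_protective = sum(dirs == "protective"),
         n_discordant = sum(dirs == "discordant"),
         retained = cand$gene[cand$retained])
  })

  if ("spatial" %in% cfg$stages) run_stage("spatial", function() {
    if (is.null(cfg$spots)) stop("spatial stage needs a 'spots' table")
    if (!file.exists(cfg$spots)) stop("spots table not found: ", cfg$spots)
    grid <- read_spot_table(cfg$spots)
    rep <- exclusion_report(grid, cfg$marker_signal, cfg$immune_signal,
                            k = cfg$k, B = cfg$B, quantile = cfg$quantile,
                            seed = seed)
    writeLines(format(rep$neighborhood$null_draws, digits = 15),
               file.path(cfg$out, "null_neighborhood.txt"))
    writeLines(format(rep$nn_distance$null_draws, digits = 15),
               file.path(cfg$out, "null_nn_distance.txt"))
    list(neighborhood_observed = rep$neighborhood$observed,
         neighborhood_pval = rep$neighborhood$pval,
         nn_distance_observed = rep$nn_distance$observed,
         nn_distance_pval = rep$nn_distance$pval,
         settings = rep$settings)
  })

  if ("strata" %in% cfg$stages) run_stage("strata", function() {
    out <- list()
    if (!is.null(cfg$mtx)) {
      m <- read_cell_matrix(cfg$mtx, cfg$genes, cfg$cells)
      part <- classify_marker_positive(m, cfg$marker_gene)
      markers <- find_markers(m, part, cfg$lfc_min, cfg$fdr_max)
      utils::write.table(markers, file.path(cfg$out, "markers.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out$n_positive_cells <- sum(part)
      out$n_marker_genes <- nrow(markers)
      out$marker_genes <- markers$gene
    }
    if (!is.null(cfg$bulk)) {
      cohort <- read_bulk_expression(cfg$bulk)
      panel <- immune_factor_panel(cohort, cfg$marker_gene, cfg$panel)
      utils::write.table(panel, file.path(cfg$out, "panel.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      out$panel <- panel
    }
    if (length(out) == 0L) stop("strata stage needs 'mtx' and/or 'bulk' inputs")
    out
  })

  write_report()
  invisible(report)
}
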
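# End-to-end orchestration: raw or synthetic records -> preprocessing ->
# structure (consensus or configured) -> CPT fitting -> descriptives,
# correlations, causal queries and the MAP dropout profile.

#' Default causal query set
#'
#' The study's result set: the effect of teenage pregnancy on dropping out
#' (outcome SS = 0, contrast TP 1 vs 0) under three single-variable
#' adjustments (Age, ES, EG), the maternal-transmission query
#' P(TP = 1 | MF = 1), and the MAP dropout profile given SS = 0.
#'
#' @return A list describing the queries, consumed by [run_pipeline()].
#' @export
default_queries <- function() {
  list(
    ace = list(
      adjust_Age = intervention_query(list(var = "SS", state = "0"), "TP",
                                      c("1", "0"), "Age"),
      adjust_ES = intervention_query(list(var = "SS", state = "0"), "TP",
                                     c("1", "0"), "ES"),
      adjust_EG = intervention_query(list(var = "SS", state = "0"), "TP",
                                     c("1", "0"), "EG")),
    conditional = list(
      tp_given_mf = list(target = "TP", state = "1",
                         evidence = list(MF = "1"))),
    map = list(dropout_profile = list(evidence = list(SS = "0"))))
}

#' Assemble a run configuration
#'
#' Exactly one input source (a raw CSV or a synthetic generator
#' configuration) and exactly one DAG source (an edge-list file, an expert
#' survey file, or a `bn_dag`; absent all three the reconstructed
#' [study_dag()] is used and flagged in the report).
#'
#' @param input_csv Path to a raw-records CSV.
#' @param generator A `generator_config` from [default_config()].
#' @param thresholds A [threshold_config()].
#' @param dag_file Path to a `parent<TAB>child` edge list.
#' @param survey_file Path to an expert survey CSV.
#' @param vote_threshold Consensus threshold for `survey_file`.
#' @param dag A `bn_dag` given directly.
#' @param pseudocount Laplace smoothing for CPT fitting. The default of 1
#'   keeps every parent configuration estimable at survey-scale sample
#'   sizes; set 0 for strict maximum likelihood.
#' @param seed Balancing seed.
#' @param queries Query list as produced by [default_queries()].
#' @return A `run_config` list.
#' @export
run_config <- function(input_csv = NULL, generator = NULL,
                       thresholds = threshold_config(),
                       dag_file = NULL, survey_file = NULL,
                       vote_threshold = 0.5, dag = NULL,
                       pseudocount = 1, seed = 1L,
                       queries = default_queries()) {
  if (is.null(input_csv) == is.null(generator)) {
    stop("supply exactly one input source: `input_csv` or `generator`",
         call. = FALSE)
  }
  if (sum(!is.null(dag_file), !is.null(survey_file), !is.null(dag)) > 1) {
    stop("supply at most one DAG source", call. = FALSE)
  }
  structure(list(input_csv = input_csv, generator = generator,
                 thresholds = thresholds, dag_file = dag_file,
                 survey_file = survey_file,
                 vote_threshold = vote_threshold, dag = dag,
                 pseudocount = pseudocount, seed = as.integer(seed),
                 queries = queries),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Recognized keys: `input_csv`, `generator` (with `n_records`,
#' `male_fraction`, `missing_rate`, `seed`), `thresholds` (with `age_cut`,
#' `income_cut`, `pregnancy_cut`), `dag_file`, `survey_file`,
#' `vote_threshold`, `pseudocount`, `seed`.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- if (!is.null(y$generator)) {
    do.call(default_config, y$generator)
  }
  thr <- if (!is.null(y$thresholds)) {
    do.call(threshold_config, y$thresholds)
  } else {
    threshold_config()
  }
  run_config(input_csv = y$input_csv, generator = gen, thresholds = thr,
             dag_file = y$dag_file, survey_file = y$survey_file,
             vote_threshold = y$vote_threshold %||% 0.5,
             pseudocount = y$pseudocount %||% 1,
             seed = y$seed %||% 1L)
}

#' Run the full causal-analysis pipeline
#'
#' Stages: obtain records (load or sample) -> preprocess (impute, exclude
#' males, balance on pregnancy, binarize) -> structure (consensus vote or
#' configured DAG) -> fit CPTs -> descriptive marginals -> correlation
#' table with spurious-correlation annotation -> ACE queries -> conditional
#' queries -> MAP profile. A stage failure is recorded in the report and
#' later stages that depend on it are skipped.
#'
#' @param cfg A [run_config()].
#' @return A `run_report` list; see [write_run_report()].
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  report <- list(tool_version = as.character(utils::packageVersion("dropoutBN")),
                 seed = cfg$seed, errors = list())
  fail <- function(stage, e) {
    report$errors[[stage]] <<- conditionMessage(e)
    NULL
  }
  records <- tryCatch({
    if (!is.null(cfg$input_csv)) {
      load_raw_records(cfg$input_csv)
    } else {
      sample_records(cfg$generator)
    }
  }, error = function(e) fail("input", e))
  report$input <- if (!is.null(records)) attr(records, "load_report")

  prep <- if (!is.null(records)) {
    tryCatch(preprocess_pipeline(records, cfg$thresholds, cfg$seed),
             error = function(e) fail("preprocess", e))
  }
  if (!is.null(prep)) {
    report$preprocess <- prep$report
    report$descriptives <- lapply(prep$table, function(x) {
      list(`0` = mean(x == 0), `1` = mean(x == 1))
    })
  }

  dag <- tryCatch({
    if (!is.null(cfg$dag)) {
      cfg$dag
    } else if (!is.null(cfg$dag_file)) {
      read_edge_list(cfg$dag_file, nodes = binary_columns)
    } else if (!is.null(cfg$survey_file)) {
      cons <- aggregate_consensus_dag(read_expert_surveys(cfg$survey_file),
                                      cfg$vote_threshold)
      report$consensus <- cons[c("votes", "dropped", "n_experts")]
      cons$dag
    } else {
      report$dag_source <- "reconstructed study DAG (study_dag)"
      study_dag()
    }
  }, error = function(e) fail("structure", e))
  if (!is.null(dag)) {
    report$dag_edges <- apply(dag$edges, 1, paste, collapse = " -> ")
  }

  corr <- if (!is.null(prep)) {
    tryCatch(correlation_table(prep$table),
             error = function(e) fail("correlations", e))
  }
  if (!is.null(corr) && !is.null(dag)) {
    corr <- annotate_spurious(corr, dag)
  }
  if (!is.null(corr)) report$correlations <- format_correlation(corr, 4)

  bn <- if (!is.null(prep) && !is.null(dag)) {
    tryCatch(fit_cpts(dag, prep$table, cfg$pseudocount),
             error = function(e) fail("fit", e))
  }

  if (!is.null(bn)) {
    report$ace <- lapply(cfg$queries$ace, function(q) {
      tryCatch({
        r <- average_causal_effect(bn, q)
        list(outcome = paste0(q$outcome$var, "=", q$outcome$state),
             treatment = q$treatment,
             adjusted_for = q$adjustment_set,
             admissible = is_backdoor_admissible(dag, q$treatment,
                                                 q$outcome$var,
                                                 q$adjustment_set),
             p_do_i = r$p_do_i, p_do_j = r$p_do_j, ace = r$ace)
      }, error = function(e) list(error = conditionMessage(e)))
    })
    report$conditional <- lapply(cfg$queries$conditional, function(q) {
      tryCatch({
        p <- query(bn, q$target, q$evidence)
        list(target = q$target, state = q$state,
             evidence = q$evidence,
             probability = unname(p[q$state]))
      }, error = function(e) list(error = conditionMessage(e)))
    })
    report$map <- lapply(cfg$queries$map, function(q) {
      tryCatch({
        m <- map_assignment(bn, q$evidence)
        list(evidence = q$evidence, assignment = m$assignment,
             probability = m$probability)
      }, error = function(e) list(error = conditionMessage(e)))
    })
  }
  structure(report, class = "run_report")
}

#' Write a run report
#'
#' Emits machine-readable JSON (`report.json`) and a short human-readable
#' summary (`summary.txt`) into `dir`.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(utils::capture.output(print(report)),
             file.path(dir, "summary.txt"))
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("== dropoutBN run report (v", x$tool_version, ", seed ", x$seed,
      ") ==\n", sep = "")
  if (!is.null(x$preprocess)) {
    p <- x$preprocess
    cat(sprintf("rows: %d loaded -> %d female -> %d balanced\n",
                p$n_loaded, p$n_after_exclusion, p$n_after_balancing))
  }
  if (!is.null(x$descriptives)) {
    cat("marginals (state 1):",
        paste(sprintf("%s %.0f%%", names(x$descriptives),
                      100 * vapply(x$descriptives, `[[`, numeric(1), "1")),
              collapse = ", "), "\n")
  }
  for (nm in names(x$ace)) {
    a <- x$ace[[nm]]
    if (!is.null(a$error)) {
      cat(sprintf("ACE %s: ERROR %s\n", nm, a$error))
    } else {
      cat(sprintf(
        "ACE of %s on %s adjusted for %s: %.2f (p_do: %.3f vs %.3f)%s\n",
        a$treatment, a$outcome, paste(a$adjusted_for, collapse = ","),
        a$ace, a$p_do_i, a$p_do_j,
        if (isTRUE(a$admissible)) "" else "  [set not backdoor-admissible]"))
    }
  }
  for (nm in names(x$conditional)) {
    q <- x$conditional[[nm]]
    if (is.null(q$error)) {
      cat(sprintf("P(%s=%s | %s) = %.3f\n", q$target, q$state,
                  paste(names(q$evidence), unlist(q$evidence), sep = "=",
                        collapse = ", "), q$probability))
    }
  }
  for (nm in names(x$map)) {
    m <- x$map[[nm]]
    if (is.null(m$error)) {
      cat(sprintf("MAP given %s: %s  (p = %.4f)\n",
                  paste(names(m$evidence), unlist(m$evidence), sep = "=",
                        collapse = ", "),
                  paste(names(m$assignment), unlist(m$assignment),
                        sep = "=", collapse = " "),
                  m$probability))
    }
  }
  if (length(x$errors)) {
    cat("stage errors:", paste(names(x$errors), unlist(x$errors),
                               sep = ": ", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Compare two run reports field by field
#'
#' @param a,b `run_report` objects answering the same query list.
#' @param tolerances Named numeric tolerances; recognized names are
#'   `counts`, `marginals`, `ace`, `probability` (defaults 0, 0.02, 0.05,
#'   0.05).
#' @return A list with `pass` (logical) and `diffs` (data frame of field,
#'   values, difference, tolerance, pass).
#' @export
compare_reports <- function(a, b, tolerances = list()) {
  tol <- utils::modifyList(list(counts = 0, marginals = 0.02, ace = 0.05,
                                probability = 0.05), tolerances)
  if (!identical(names(a$ace), names(b$ace)) ||
      !identical(names(a$conditional), names(b$conditional)) ||
      !identical(names(a$map), names(b$map))) {
    stop("reports answer different query lists", call. = FALSE)
  }
  rows <- list()
  add <- function(field, va, vb, t) {
    rows[[length(rows) + 1]] <<- data.frame(
      field = field, a = va, b = vb, diff = abs(va - vb), tol = t,
      pass = abs(va - vb) <= t, stringsAsFactors = FALSE)
  }
  for (f in c("n_loaded", "n_after_exclusion", "n_after_balancing")) {
    if (!is.null(a$preprocess[[f]]) && !is.null(b$preprocess[[f]])) {
      add(f, a$preprocess[[f]], b$preprocess[[f]], tol$counts)
    }
  }
  for (v in intersect(names(a$descriptives), names(b$descriptives))) {
    add(paste0("marginal_", v), a$descriptives[[v]][["1"]],
        b$descriptives[[v]][["1"]], tol$marginals)
  }
  for (nm in names(a$ace)) {
    if (is.null(a$ace[[nm]]$error) && is.null(b$ace[[nm]]$error)) {
      add(paste0("ace_", nm), a$ace[[nm]]$ace, b$ace[[nm]]$ace, tol$ace)
    }
  }
  for (nm in names(a$conditional)) {
    if (is.null(a$conditional[[nm]]$error) &&
        is.null(b$conditional[[nm]]$error)) {
      add(paste0("p_", nm), a$conditional[[nm]]$probability,
          b$conditional[[nm]]$probability, tol$probability)
    }
  }
  diffs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(field = character(0), a = numeric(0), b = numeric(0),
               diff = numeric(0), tol = numeric(0), pass = logical(0))
  list(pass = all(diffs$pass), diffs = diffs)
}
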
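## Orchestration: per-polymorph characterization reports and the
## pipeline entry point used by the command-line wrapper.

#' Characterize one fibril model
#'
#' Full annotation of a single atomic model: fitted helical parameters,
#' implied cross-over distance, beta-strand segments, inter-subunit
#' contacts, K28-D23 salt bridge, and (for two-subunit models) the
#' herringbone angle over the ordered range.
#'
#' @param m a [fibril_model()].
#' @param ordered_range residue range used for the molecular axis; default
#'   the full common resolved range.
#' @param contact_cutoff,salt_cutoff distance cutoffs in Angstrom.
#' @return list of class `fibril_characterization`.
#' @export
characterize_fibril <- function(m, ordered_range = NULL,
                                contact_cutoff = 5.0, salt_cutoff = 4.0) {
  if (is.null(m$subunit)) m <- infer_layers_and_subunits(m)
  hp <- fit_helical_params(m)
  if (is.null(ordered_range)) {
    rr <- range(m$atoms$resno)
    ordered_range <- c(rr[1], rr[2])
  }
  segs <- beta_strand_segments(m)
  two_sub <- length(unique(m$subunit)) >= 2
  herring <- if (two_sub) tryCatch(herringbone_angle(m, ordered_range),
                                   error = function(e) NA_real_) else NA_real_
  contacts <- if (two_sub) tryCatch(contact_map(m, cutoff = contact_cutoff,
                                                salt_cutoff = salt_cutoff),
                                    error = function(e) NULL) else NULL
  sb <- salt_bridge(m, cutoff = salt_cutoff)
  out <- list(helical = hp,
              crossover_nm = crossover_distance(hp),
              strands = segs,
              herringbone_deg = herring,
              contacts = contacts,
              salt_bridge = sb,
              ordered_range = ordered_range,
              cutoffs = list(contact = contact_cutoff, salt = salt_cutoff))
  class(out) <- "fibril_characterization"
  out
}

#' @export
print.fibril_characterization <- function(x, ...) {
  hp <- x$helical
  d <- x$crossover_nm
  cat(sprintf("Symmetry %s; twist %.3f deg, rise %.3f A; cross-over %s\n",
              hp$symmetry, hp$twist, hp$rise,
              if (is.infinite(d)) "infinite (untwisted)"
              else sprintf("%.1f nm (~%d nm)", d, round(d))))
  if (nrow(x$strands)) {
    by_sub <- split(x$strands, x$strands$subunit)
    for (s in names(by_sub)) {
      cat(sprintf("  beta strands [%s]: %s\n", s,
                  paste(sprintf("%d-%d", by_sub[[s]]$start, by_sub[[s]]$end),
                        collapse = ", ")))
    }
  }
  if (!is.na(x$herringbone_deg)) {
    cat(sprintf("  herringbone angle: %.2f deg (residues %d-%d)\n",
                x$herringbone_deg, x$ordered_range[1], x$ordered_range[2]))
  }
  if (!is.null(x$contacts) && nrow(x$contacts)) {
    cat(sprintf("  inter-subunit contacts <= %.1f A: %d pairs (%d hydrophobic, %d salt bridge)\n",
                x$cutoffs$contact, nrow(x$contacts),
                sum(x$contacts$class == "hydrophobic"),
                sum(x$contacts$class == "salt_bridge")))
  }
  if (!is.na(x$salt_bridge$present)) {
    cat(sprintf("  K28-D23 salt bridge: %s (mean min N-O %.2f A)\n",
                if (x$salt_bridge$present) "present" else "absent",
                x$salt_bridge$dist))
  }
  invisible(x)
}

#' Run the analysis pipeline over parameter tables and models
#'
#' Orchestrates the characterization workflow: a cross-over table for every
#' row of a polymorph parameter table, a full annotation of every supplied
#' atomic model, and pairwise superposition comparisons when two or more
#' models are given. Reports are written as TSV and JSON into `out_dir`
#' (when given), with every cutoff recorded for provenance.
#'
#' @param config list with optional entries: `polymorph_table` (data.frame
#'   or path readable by [read_polymorph_table()]), `models` (character
#'   vector of PDB/mmCIF paths), `ordered_range`, `fit_range`,
#'   `score_range`, `selection`, `contact_cutoff`, `salt_cutoff`,
#'   `out_dir`.
#' @return list of class `pipeline_report` with `crossover`,
#'   `characterizations`, `comparisons`, `config`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(polymorph_table = NULL, models = character(),
                                ordered_range = NULL,
                                fit_range = NULL, score_range = NULL,
                                selection = "heavy",
                                contact_cutoff = 5.0, salt_cutoff = 4.0,
                                out_dir = NULL), config)
  report <- list(config = cfg)

  tab <- cfg$polymorph_table
  if (is.character(tab)) tab <- read_polymorph_table(tab)
  if (!is.null(tab)) report$crossover <- crossover_report(tab)

  if (length(cfg$models)) {
    missing <- cfg$models[!file.exists(cfg$models)]
    if (length(missing)) stop("missing input file(s): ",
                              paste(missing, collapse = ", "), call. = FALSE)
    ms <- lapply(cfg$models, read_fibril_model)
    names(ms) <- basename(cfg$models)
    report$characterizations <- lapply(ms, characterize_fibril,
                                       ordered_range = cfg$ordered_range,
                                       contact_cutoff = cfg$contact_cutoff,
                                       salt_cutoff = cfg$salt_cutoff)
    if (length(ms) >= 2) {
      cmp <- list()
      for (i in seq_len(length(ms) - 1)) for (j in seq(i + 1, length(ms))) {
        fr <- cfg$fit_range %||% range(intersect(ms[[i]]$atoms$resno,
                                                 ms[[j]]$atoms$resno))
        r <- superpose_rmsd(ms[[i]], ms[[j]], fit_range = fr,
                            score_range = cfg$score_range %||% fr,
                            selection = cfg$selection)
        cmp[[paste(names(ms)[i], names(ms)[j], sep = " vs ")]] <-
          list(rmsd = r$rmsd, n_score = r$n_score, fit_range = fr)
      }
      report$comparisons <- cmp
    }
  }
  if (is.null(tab) && !length(cfg$models)) {
    warning("empty input: no polymorph table and no models; empty report")
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(report$crossover)) {
      utils::write.table(report$crossover,
                         file.path(cfg$out_dir, "crossover.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    json <- list(config = cfg[setdiff(names(cfg), "polymorph_table")],
                 crossover = report$crossover,
                 comparisons = report$comparisons)
    jsonlite::write_json(json, file.path(cfg$out_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE, null = "null")
  }
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  if (!is.null(x$crossover)) {
    cat("Cross-over table (", nrow(x$crossover), " polymorphs):\n", sep = "")
    print(x$crossover[, intersect(c("name", "twist_deg", "rise_A", "symmetry",
                                    "crossover_round_nm", "consistent"),
                                  names(x$crossover))])
  }
  for (nm in names(x$characterizations)) {
    cat("\n== ", nm, " ==\n", sep = "")
    print(x$characterizations[[nm]])
  }
  for (nm in names(x$comparisons)) {
    cat(sprintf("\n%s: RMSD %.2f A over %d atoms\n", nm,
                x$comparisons[[nm]]$rmsd, x$comparisons[[nm]]$n_score))
  }
  invisible(x)
}
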
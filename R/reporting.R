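#' Flag disagreements between recomputed and printed isolation statistics
#'
#' Joins the recomputed per-pair statistics to a printed-values table (as
#' strings, so printed precision is known) and lists every cell whose
#' recomputed value falls outside one unit in the printed value's last
#' decimal -- the package never corrects a printed table silently, it
#' reports both numbers. On the bundled strain-pair fixture this surfaces
#' the known printing inconsistencies of the source tables: the
#' transposed sex-specific indices of the BAJ x GUR row, the OAX x TEH and
#' OAX x SON chi-squares, and the TEH x SON chi-square (whose printed
#' value used the printed total rather than the sum of its own counts).
#'
#' @param results an `isolation_result` data frame from
#'   [analyze_trials()].
#' @param published data frame read from a printed-statistics CSV with
#'   columns `strain_a,strain_b,chi2,I,SE_I,I1,SE_I1,I2,SE_I2` (values as
#'   printed).
#' @return data frame with columns `strain_a, strain_b, statistic,
#'   printed, recomputed`; zero rows when everything agrees.
#' @export
compare_isolation_published <- function(results, published) {
  stats_map <- c(chi2 = "chi2", I = "I", SE_I = "SE_I", I1 = "I1",
                 SE_I1 = "SE_I1", I2 = "I2", SE_I2 = "SE_I2")
  out <- list()
  for (i in seq_len(nrow(published))) {
    j <- which(results$strain_a == published$strain_a[i] &
               results$strain_b == published$strain_b[i])
    if (!length(j)) next
    for (s in names(stats_map)) {
      if (!s %in% names(published)) next
      printed <- as.character(published[[s]][i])
      comp <- results[[stats_map[[s]]]][j]
      ok <- matches_printed(comp, printed)
      if (isFALSE(ok))
        out[[length(out) + 1]] <- data.frame(
          strain_a = published$strain_a[i], strain_b = published$strain_b[i],
          statistic = s, printed = printed, recomputed = comp,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(strain_a = character(), strain_b = character(),
                      statistic = character(), printed = character(),
                      recomputed = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Flag disagreements between recomputed and printed sex-ratio chi-squares
#'
#' Same policy as [compare_isolation_published()], for the cross table.
#' On the bundled homotypic-cross fixture this surfaces the GUR x GUR
#' chi-square, whose printed value (6.08) is not reproducible from the
#' printed offspring counts under any standard 1:1 test.
#'
#' @param results a `fertility_result` data frame from
#'   [analyze_crosses()].
#' @param published data frame with columns `mother,father,chi2` (printed
#'   strings).
#' @return data frame of mismatches as in [compare_isolation_published()].
#' @export
compare_crosses_published <- function(results, published) {
  out <- list()
  for (i in seq_len(nrow(published))) {
    j <- which(results$mother == published$mother[i] &
               results$father == published$father[i])
    if (!length(j)) next
    printed <- as.character(published$chi2[i])
    comp <- results$chi2_sex[j]
    if (isFALSE(matches_printed(comp, printed)))
      out[[length(out) + 1]] <- data.frame(
        strain_a = published$mother[i], strain_b = published$father[i],
        statistic = "chi2_sex", printed = printed, recomputed = comp,
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(strain_a = character(), strain_b = character(),
                      statistic = character(), printed = character(),
                      recomputed = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Run the full analysis pipeline from a configuration file
#'
#' Reads a `key=value` configuration (see [read_config()]) naming any of
#' `trials`, `crosses`, `alignment` (plus optional `group_map`,
#' `published_trials`, `published_crosses`, `seed`, `digits`, `out_dir`)
#' and runs every stage for which an input is present. When an input file
#' is byte-identical to a bundled fixture, its printed-values table is
#' compared automatically and every printed-vs-recomputed mismatch beyond
#' rounding ends up in `warnings`. Outputs are deterministic: rerunning
#' the same configuration reproduces the report byte for byte.
#'
#' @param config path to the configuration file.
#' @return a `run_report` list: `isolation`, `fertility`, `divergence`,
#'   `network`, `discrepancies` (data frame), `warnings` (character),
#'   `meta` (input hashes, seed, package version), `config` (parsed).
#' @export
run_pipeline <- function(config) {
  cfg <- read_config(config)
  inputs <- intersect(c("trials", "crosses", "alignment"), names(cfg))
  if (!length(inputs))
    abort("config must name at least one input: trials, crosses or alignment",
          "reproiso_config_error")
  missing <- cfg[inputs][!file.exists(cfg[inputs])]
  if (length(missing))
    abort(sprintf("config input file(s) not found: %s",
                  paste(sprintf("%s=%s", names(missing), missing),
                        collapse = ", ")), "reproiso_config_error")

  warn_log <- character(0)
  note <- function(msg) warn_log <<- c(warn_log, msg)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    note(conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  iso <- fert <- dm <- net <- NULL
  disc <- list()
  fixture_md5 <- function(name) unname(tools::md5sum(reproiso_example(name)))

  if ("trials" %in% names(cfg)) {
    trials <- collect(read_mating_trials(cfg[["trials"]]))
    iso <- analyze_trials(trials)
    pub_path <- cfg["published_trials"]
    if (is.na(pub_path) &&
        unname(tools::md5sum(cfg[["trials"]])) ==
          fixture_md5("mating_trials_table3.csv"))
      pub_path <- reproiso_example("table3_published.csv")
    if (!is.na(pub_path)) {
      pub <- utils::read.csv(pub_path, colClasses = "character")
      disc[[length(disc) + 1]] <- compare_isolation_published(iso, pub)
    }
  }
  if ("crosses" %in% names(cfg)) {
    crosses <- collect(read_cross_records(cfg[["crosses"]]))
    fert <- analyze_crosses(crosses)
    pub_path <- cfg["published_crosses"]
    if (is.na(pub_path) &&
        unname(tools::md5sum(cfg[["crosses"]])) ==
          fixture_md5("crosses_table2a.csv"))
      pub_path <- reproiso_example("table2a_published.csv")
    if (!is.na(pub_path)) {
      pub <- utils::read.csv(pub_path, colClasses = "character")
      disc[[length(disc) + 1]] <- compare_crosses_published(fert, pub)
    }
  }
  if ("alignment" %in% names(cfg)) {
    gmap <- NULL
    if ("group_map" %in% names(cfg)) {
      gm <- utils::read.csv(cfg[["group_map"]], colClasses = "character")
      gmap <- stats::setNames(gm[[2]], gm[[1]])
    }
    aln <- collect(read_fasta_alignment(cfg[["alignment"]], group_map = gmap))
    dm <- group_divergence_matrix(aln)
    haps <- collapse_haplotypes(aln)
    limit <- if ("connection_limit" %in% names(cfg))
      as.integer(cfg[["connection_limit"]]) else NULL
    net <- build_network(haps, connection_limit = limit)
  }

  disc <- if (length(disc)) do.call(rbind, disc) else
    data.frame(strain_a = character(), strain_b = character(),
               statistic = character(), printed = character(),
               recomputed = numeric(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(disc)))
    note(sprintf("printed %s for %s x %s is %s; recomputed %.4f",
                 disc$statistic[i], disc$strain_a[i], disc$strain_b[i],
                 disc$printed[i], disc$recomputed[i]))

  meta <- list(
    inputs = vapply(cfg[inputs], function(p) unname(tools::md5sum(p)), ""),
    seed = if ("seed" %in% names(cfg)) as.integer(cfg[["seed"]]) else NA_integer_,
    package_version = as.character(utils::packageVersion("reproiso")))

  structure(list(isolation = iso, fertility = fert, divergence = dm,
                 network = net, discrepancies = disc, warnings = warn_log,
                 meta = meta, config = cfg),
            class = "run_report")
}

#' Render a run report to publication-style tables
#'
#' Writes, for whichever stages the report contains: `isolation.csv` and
#' `isolation.md` (column order mirroring the choice-test table: counts,
#' chi-square, `I (SE)`, `I1 (SE)`, `I2 (SE)`, with `*` marking indices at
#' least twice their SE and p-values printed so the caller applies their
#' own alpha), `fertility.csv`/`fertility.md`, `divergence.csv`,
#' `network.tsv`, plus `warnings.txt` and a `run.log` recording input
#' hashes, seed and package version. Files contain no timestamps, so
#' reruns are byte-identical.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @param digits decimals for indices and chi-squares (default 2,
#'   mirroring the published tables; internal values stay full-precision).
#' @return character vector of files written, invisibly.
#' @export
render_tables <- function(report, out_dir, digits = 2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(name) {
    p <- file.path(out_dir, name)
    written <<- c(written, p)
    p
  }
  fmt <- function(x, d = digits)
    ifelse(is.na(x), "-", formatC(round_half_away(x, d), format = "f",
                                  digits = d))
  fmt_ise <- function(i, se, sig)
    ifelse(is.na(i), "-",
           sprintf("%s (%s)%s", fmt(i), fmt(se), ifelse(sig, "*", "")))

  if (!is.null(report$isolation)) {
    iso <- report$isolation
    utils::write.csv(as.data.frame(iso), emit("isolation.csv"),
                     row.names = FALSE, quote = FALSE)
    md <- c("| A | B | N | chi2 | p | I (SE) | I1 (SE) | I2 (SE) |",
            "|---|---|---|------|---|--------|---------|---------|",
            sprintf("| %s | %s | %d | %s | %s | %s | %s | %s |",
                    iso$strain_a, iso$strain_b, iso$n,
                    fmt(iso$chi2), fmt(iso$p_value, 4),
                    fmt_ise(iso$I, iso$SE_I, iso$significant_I),
                    fmt_ise(iso$I1, iso$SE_I1, iso$significant_I1),
                    fmt_ise(iso$I2, iso$SE_I2, iso$significant_I2)))
    writeLines(md, emit("isolation.md"))
  }
  if (!is.null(report$fertility)) {
    fert <- report$fertility
    utils::write.csv(as.data.frame(fert), emit("fertility.csv"),
                     row.names = FALSE, quote = FALSE)
    md <- c("| Mother | Father | Offspring | chi2 | p | Motile | 95% CI | Category |",
            "|--------|--------|-----------|------|---|--------|--------|----------|",
            sprintf("| %s | %s | %d | %s | %s | %s | %s | %s |",
                    fert$mother, fert$father, fert$total_offspring,
                    fmt(fert$chi2_sex), fmt(fert$p_value, 4),
                    fmt(fert$motile_fraction),
                    ifelse(is.na(fert$ci_low), "-",
                           sprintf("[%s, %s]", fmt(fert$ci_low),
                                   fmt(fert$ci_high))),
                    fert$category))
    writeLines(md, emit("fertility.md"))
  }
  if (!is.null(report$divergence))
    write_divergence_csv(report$divergence, emit("divergence.csv"),
                         digits = digits)
  if (!is.null(report$network))
    write_network_tsv(report$network, emit("network.tsv"))

  writeLines(report$warnings, emit("warnings.txt"))
  log <- c(sprintf("reproiso %s", report$meta$package_version),
           sprintf("seed: %s", report$meta$seed),
           sprintf("input %s: md5 %s", names(report$meta$inputs),
                   report$meta$inputs))
  writeLines(log, emit("run.log"))
  invisible(written)
}
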
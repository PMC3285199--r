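#' Force-field score cards
#'
#' Each force field gets an integer 0-2 per test battery (folded-protein
#' NMR agreement, peptide secondary-structure propensities, folding of
#' villin and the WW domain) -- 0 for reasonable agreement with experiment,
#' 1 for some agreement, 2 for severe discrepancies -- and a total that is
#' their sum (0-6, lower is better).
#'
#' @param force_field force-field labels.
#' @param year publication year (for multiply-corrected force fields, the
#'   year of the most recent correction).
#' @param s_folded,s_peptides,s_folding per-test integer scores in
#'   \{0, 1, 2\}.
#' @return data.frame of class `score_card` with a `total` column.
#' @export
score_card <- function(force_field, year, s_folded, s_peptides, s_folding) {
  df <- data.frame(force_field = as.character(force_field),
                   year = as.integer(year),
                   s_folded = as.integer(s_folded),
                   s_peptides = as.integer(s_peptides),
                   s_folding = as.integer(s_folding),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$force_field))
    stop("duplicate force-field labels")
  df$total <- mapply(function(s1, s2, s3) aggregate_score(c(s1, s2, s3)),
                     df$s_folded, df$s_peptides, df$s_folding)
  class(df) <- c("score_card", "data.frame")
  df
}

#' Sum a per-test score triple
#'
#' @param per_test integer vector of three per-test scores, each in
#'   \{0, 1, 2\}.
#' @return integer total in [0, 6].
#' @export
aggregate_score <- function(per_test) {
  if (length(per_test) != 3 || !all(per_test %in% 0:2))
    stop("per_test must be three integers in {0, 1, 2}")
  as.integer(sum(per_test))
}

#' Packaged published score triples
#'
#' The manually assigned per-test scores and totals for the eight force
#' fields evaluated in the original study, with the publication year of
#' each force field's most recent correction. These scores were assigned
#' subjectively by the study's authors and are shipped as a fixture; they
#' are never derived from data by this package (see [apply_rubric()] for a
#' reproducible alternative).
#'
#' @return a [score_card] with eight rows.
#' @export
ff_score_fixture <- function() {
  path <- system.file("extdata", "force_field_scores.tsv",
                      package = "ffvalidate", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = TRUE)
  score_card(df$force_field, df$year, df$s_folded, df$s_peptides,
             df$s_folding)
}

#' Rank force fields by total score
#'
#' Ascending total (low = good agreement); ties share the minimum rank
#' (competition ranking) and the input order is preserved within ties.
#'
#' @param cards a [score_card].
#' @return the cards sorted by total, with a `rank` column.
#' @export
rank_force_fields <- function(cards) {
  if (!nrow(cards)) stop("empty score-card list")
  if (anyDuplicated(cards$force_field))
    stop("duplicate force-field labels")
  ord <- order(cards$total, seq_len(nrow(cards)))
  out <- cards[ord, , drop = FALSE]
  out$rank <- rank(out$total, ties.method = "min")
  rownames(out) <- NULL
  out
}

#' Rank correlation between publication year and total score
#'
#' Spearman rank correlation; a negative value means later force fields
#' score better (lower), i.e. force fields have improved over time.
#'
#' @param cards a [score_card] with at least 3 distinct years.
#' @return Spearman rho (0 with a warning when either variable is
#'   constant).
#' @export
score_year_trend <- function(cards) {
  if (length(unique(cards$year)) < 3)
    stop("need at least 3 distinct years for a trend")
  rho <- suppressWarnings(
    stats::cor(cards$year, cards$total, method = "spearman"))
  if (is.na(rho)) {
    warning("degenerate trend (constant scores); returning 0")
    rho <- 0
  }
  rho
}

#' Rubric thresholds for reproducible scoring
#'
#' The published scores were assigned manually; this rubric offers a
#' deterministic alternative: each test's continuous badness metric (e.g.
#' mean Q factor, helicity deviation, missed folding events) is mapped to
#' \{0, 1, 2\} by two strictly increasing cut-points. A metric exactly on a
#' cut-point goes to the lower score class (closed lower intervals).
#'
#' @param folded,peptides,folding numeric length-2 increasing cut-points
#'   for the three tests.
#' @param version label recorded in rubric output.
#' @return list of class `rubric_thresholds`.
#' @export
rubric_thresholds <- function(folded, peptides, folding,
                              version = "ffvalidate-rubric-1") {
  for (cp in list(folded, peptides, folding))
    if (length(cp) != 2 || diff(cp) <= 0)
      stop("each test needs two strictly increasing cut-points")
  structure(list(folded = folded, peptides = peptides, folding = folding,
                 version = version), class = "rubric_thresholds")
}

#' Map continuous per-test metrics to a score triple
#'
#' @param metrics named list or vector with elements `folded`, `peptides`,
#'   `folding` (higher = worse agreement).
#' @param rubric a [rubric_thresholds].
#' @return integer triple (named) with attribute `"rubric_version"`.
#' @export
apply_rubric <- function(metrics, rubric) {
  stopifnot(inherits(rubric, "rubric_thresholds"))
  need <- c("folded", "peptides", "folding")
  metrics <- as.list(metrics)
  if (!all(need %in% names(metrics)) ||
      any(!vapply(metrics[need], function(x) is.finite(as.numeric(x)), TRUE)))
    stop("metrics must supply finite values for ",
         paste(need, collapse = ", "))
  out <- vapply(need, function(t)
    sum(as.numeric(metrics[[t]]) > rubric[[t]]), numeric(1))
  out <- as.integer(out)
  names(out) <- need
  attr(out, "rubric_version") <- rubric$version
  out
}

# Tiny deterministic polynomial hash of deparsed inputs, used to stamp
# report files with a provenance token.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

render_cell <- function(n_fold, n_unfold) {
  if (n_fold >= 1) sprintf("\u2713 (%d/%d)", n_fold, n_unfold) else "\u2717"
}

#' Render the comparison report bundle
#'
#' Writes deterministic CSV tables plus a Markdown summary: the
#' NMR-agreement panel (bar-chart data), melting curves, the
#' folding-event grid in the check-mark "(n_fold/n_unfold)" convention,
#' and the score cards with ranking and year trend. Every file is stamped
#' with the package version and a hash of the inputs.
#'
#' @param dir output directory (created if needed).
#' @param panels optional `agreement_panel` (or rbind of several).
#' @param curves optional named list of [melting_curve]s.
#' @param events optional data.frame with columns `force_field`, `system`,
#'   `n_fold`, `n_unfold`.
#' @param cards optional [score_card].
#' @return invisible character vector of files written.
#' @export
render_report <- function(dir, panels = NULL, curves = NULL, events = NULL,
                          cards = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- paste0("ffvalidate ",
                  as.character(utils::packageVersion("ffvalidate")),
                  " config ",
                  config_hash(list(panels, curves, events, cards)))
  written <- character(0)
  put_csv <- function(df, name) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    writeLines(paste("#", stamp), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    written <<- c(written, path)
  }
  md <- c("# Force-field validation report", "", paste0("_", stamp, "_"), "")

  if (!is.null(panels)) {
    put_csv(panels, "agreement_panel.csv")
    md <- c(md, "## NMR observable agreement", "",
            md_table(panels[c("system", "observable", "value", "sem")]), "")
  }
  if (!is.null(curves) && length(curves)) {
    all_curves <- do.call(rbind, lapply(names(curves), function(nm)
      cbind(system = nm, as.data.frame(curves[[nm]]))))
    put_csv(all_curves, "melting_curves.csv")
    md <- c(md, "## Melting curves", "",
            md_table(all_curves[c("system", "temperature", "fraction",
                                  "sem")]), "")
  } else if (!is.null(curves)) {
    message("no melting curves supplied; curves table omitted")
  }
  if (!is.null(events)) {
    events$cell <- mapply(render_cell, events$n_fold, events$n_unfold)
    put_csv(events, "folding_events.csv")
    wide <- stats::reshape(
      events[c("force_field", "system", "cell")],
      idvar = "force_field", timevar = "system", direction = "wide")
    names(wide) <- sub("^cell\\.", "", names(wide))
    md <- c(md, "## Folding events", "", md_table(wide), "",
            paste0("A check mark means at least one folding event was ",
                   "detected; numbers are (folding/unfolding) event ",
                   "counts."), "")
  }
  if (!is.null(cards)) {
    ranked <- rank_force_fields(cards)
    put_csv(ranked, "score_cards.csv")
    md <- c(md, "## Force-field scores (0-6, lower is better)", "",
            md_table(ranked), "")
    if (length(unique(cards$year)) >= 3) {
      rho <- score_year_trend(cards)
      md <- c(md, sprintf(
        "Spearman rank correlation of total score with year: %.3f", rho), "")
    } else {
      message("fewer than 3 distinct years; trend step skipped")
    }
  }
  path <- file.path(dir, "report.md")
  writeLines(md, path)
  written <- c(written, path)
  invisible(written)
}

md_table <- function(df) {
  fmt <- function(x) if (is.numeric(x)) formatC(x, format = "g", digits = 4)
                     else as.character(x)
  body <- do.call(cbind, lapply(df, fmt))
  body <- matrix(body, nrow = nrow(df),
                 dimnames = list(NULL, names(df)))
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(body, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}
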
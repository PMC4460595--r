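safe_filename <- function(label) gsub("[^A-Za-z0-9._-]", "_", label)

#' Persist a trained model to a directory
#'
#' Writes a JSON manifest (format version, family labels and files, the full
#' pyramid configuration, provenance) plus one dense TSV weight matrix per
#' family (ids as header row and first column). Everything is plain text.
#'
#' @param model A `gp_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_model()]
#' @export
write_model <- function(model, dir) {
  stopifnot(inherits(model, "gp_model"))
  dir.create(file.path(dir, "families"), recursive = TRUE, showWarnings = FALSE)
  files <- setNames(
    sprintf("families/%s.tsv", vapply(model_labels(model), safe_filename, character(1))),
    model_labels(model)
  )
  if (anyDuplicated(files)) {
    abort("family labels collide after filename sanitization.",
      class = "ppsnet_model_error"
    )
  }
  for (lab in model_labels(model)) {
    utils::write.table(
      model$families[[lab]]$weights,
      file.path(dir, files[[lab]]),
      sep = "\t", quote = FALSE, col.names = NA
    )
  }
  cfg <- model$config
  manifest <- list(
    format_version = 1L,
    families = lapply(model_labels(model), function(lab) {
      list(
        label = lab, file = files[[lab]],
        ids = model$families[[lab]]$ids
      )
    }),
    config = list(
      n_levels = cfg$n_levels, T_ac = cfg$T_ac, T_rc = cfg$T_rc, p = cfg$p,
      r_low = cfg$r_low, r_high = cfg$r_high, k = cfg$k,
      weighted_ge = cfg$weighted_ge, ge_descend = cfg$ge_descend,
      global_ladder = cfg$global_ladder, ladders = cfg$ladders
    ),
    provenance = model$provenance
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Load a model written by [write_model()]
#'
#' @param dir Model directory containing `manifest.json`.
#' @return A `gp_model`.
#' @export
read_model <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) {
    abort(sprintf("no manifest.json under '%s'.", dir), class = "ppsnet_model_error")
  }
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(as.integer(manifest$format_version), 1L)) {
    abort("unsupported model format version.", class = "ppsnet_model_error")
  }
  graphs <- lapply(manifest$families, function(fam) {
    w <- as.matrix(utils::read.delim(file.path(dir, fam$file),
      row.names = 1L, check.names = FALSE
    ))
    ids <- as.character(fam$ids)
    if (!identical(rownames(w), ids) || !identical(colnames(w), ids)) {
      abort(
        sprintf("weight matrix of family '%s' does not match manifest ids.", fam$label),
        class = "ppsnet_model_error"
      )
    }
    new_family_graph(fam$label, ids, w)
  })
  names(graphs) <- vapply(manifest$families, `[[`, character(1), "label")
  mc <- manifest$config
  cfg <- pyramid_config(
    n_levels = mc$n_levels, T_ac = mc$T_ac, T_rc = mc$T_rc, p = mc$p,
    r_low = mc$r_low, r_high = mc$r_high, k = mc$k,
    weighted_ge = isTRUE(mc$weighted_ge), ge_descend = isTRUE(mc$ge_descend)
  )
  cfg$global_ladder <- as.numeric(mc$global_ladder)
  cfg$ladders <- lapply(mc$ladders[gsf_names()], as.numeric)
  structure(
    list(
      families = graphs, config = cfg,
      provenance = manifest$provenance,
      cache = new.env(parent = emptyenv())
    ),
    class = "gp_model"
  )
}

#' Read a sequence-to-family membership table
#'
#' @param path Headered TSV with columns `seq_id`, `family_id`.
#' @return A tibble with character columns `seq_id`, `family_id`.
#' @export
read_families <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: '%s'.", path), class = "ppsnet_format_error")
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("seq_id", "family_id") %in% names(df))) {
    abort("families table must have columns seq_id and family_id.",
      class = "ppsnet_format_error"
    )
  }
  tibble(seq_id = as.character(df$seq_id), family_id = as.character(df$family_id))
}

#' Read and write similarity tables as TSV
#'
#' The on-disk form is a headered TSV with columns `id_a`, `id_b`, `eb`
#' (one row per unordered pair with a positive EB-score).
#'
#' @param table A `pps_similarity` table.
#' @param path File path.
#' @return `write_similarity()` returns `path` invisibly;
#'   `read_similarity()` returns a `pps_similarity` tibble.
#' @export
write_similarity <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: '%s'.", path), class = "ppsnet_format_error")
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("id_a", "id_b", "eb") %in% names(df))) {
    abort("similarity TSV must have columns id_a, id_b, eb.",
      class = "ppsnet_format_error"
    )
  }
  as_score_table(tibble(
    id_a = as.character(df$id_a), id_b = as.character(df$id_b),
    eb = as.numeric(df$eb)
  ))
}

#' Write predictions as TSV
#'
#' One row per query: the predicted family (empty for no decision), the
#' decision status against the truth labels when supplied (`cd`/`wd`/`nd`),
#' the per-feature `t*` levels and the pooled votes as a JSON array.
#'
#' @param predictions A `gp_predictions` tibble from [classify()].
#' @param path Output path.
#' @param truth Optional data frame `query_id`, `family_id`.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, truth = NULL) {
  out <- tibble(
    query_id = predictions$query_id,
    predicted_family = ifelse(is.na(predictions$predicted), "", predictions$predicted),
    status = NA_character_,
    t_star_ac = predictions$t_star_ac,
    t_star_rc = predictions$t_star_rc,
    t_star_sm = predictions$t_star_sm,
    t_star_tr = predictions$t_star_tr,
    t_star_ge = predictions$t_star_ge,
    votes_json = vapply(
      predictions$votes,
      function(v) as.character(jsonlite::toJSON(as.character(v))), character(1)
    )
  )
  if (!is.null(truth)) {
    rep <- evaluate_predictions(predictions, truth)
    out$status <- rep$decisions$status[match(out$query_id, rep$decisions$query_id)]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
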
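# End-to-end orchestration: template indexing, input parsing, chunked and
# cached annotation, and the TSV writers.

#' Default pipeline configuration
#'
#' @param ... named overrides of the defaults.
#' @return named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    identity_threshold = 0.35,  # acceptance (inclusive)
    own_structure_identity = 0.99,
    k = 5,                      # candidate-search k-mer size
    gap_open = 10, gap_extend = 0.5,
    n_points = 960, probe = 1.4,
    dist_cutoff = 5.0, radius = 10.0, sep_threshold = 6,
    rsa_threshold = 0.16, degree_eps = 0.1,
    chunk_size = 100, workers = 1,
    mode = "default",           # "default" (cached) or "lite"
    cache_dir = NULL,
    seed = 1,
    verbosity = "warn"
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Build (or load) the template library index
#'
#' Scans a directory of PDB-format files and writes a tab-separated sidecar
#' \code{template_index.tsv} with one row per protein chain: entry id,
#' chain id, ATOM-derived sequence, residue numbering, resolution and file
#' path. An existing sidecar is reused unless \code{force}.
#'
#' @param template_dir directory containing \code{.pdb} files.
#' @param force rebuild even if the sidecar exists.
#' @return data frame index.
#' @export
build_template_index <- function(template_dir, force = FALSE) {
  sidecar <- file.path(template_dir, "template_index.tsv")
  if (file.exists(sidecar) && !force) {
    return(utils::read.delim(sidecar, colClasses = "character"))
  }
  files <- list.files(template_dir, pattern = "\\.(pdb|ent)$",
                      full.names = TRUE, ignore.case = TRUE)
  rows <- list()
  for (f in sort(files)) {
    model <- tryCatch(parse_structure(f), error = function(e) NULL)
    if (is.null(model)) next
    for (ch in model$chains) {
      if (ch$entity_type != "protein") next
      sq <- extract_atom_sequence(model, ch$chain_id)
      if (nchar(sq$sequence) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        entry_id = model$entry_id, chain_id = ch$chain_id,
        sequence = sq$sequence,
        resnums = paste(sq$resnum, collapse = ","),
        icodes = paste(sq$icode, collapse = ","),
        resolution = as.character(model$resolution),
        path = f, stringsAsFactors = FALSE)
    }
  }
  index <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(entry_id = character(0), chain_id = character(0),
               sequence = character(0), resnums = character(0),
               icodes = character(0), resolution = character(0),
               path = character(0), stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(index, sidecar, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  index
}

#' Parse a tab-separated mutation list
#'
#' Lines are \code{protein-id<TAB>variant<TAB>tags}; variant and tags are
#' optional. A blank variant column queries every position of the protein.
#'
#' @param path input file path.
#' @return data frame with columns \code{input_id}, \code{variant_text},
#'   \code{tags}.
#' @export
parse_mutation_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  out <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) == 0 || trimws(parts[1]) == "") {
      stop("malformed mutation-list line ", i, ": '", lines[i], "'")
    }
    data.frame(input_id = trimws(parts[1]),
               variant_text = if (length(parts) >= 2) trimws(parts[2])
                              else "",
               tags = if (length(parts) >= 3) trimws(parts[3]) else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Parse FASTA input into query proteins and variants
#'
#' The first header token is the protein id; any further tokens are parsed
#' as variant strings.
#'
#' @param path FASTA file path.
#' @return list with \code{sequences} (named character vector) and
#'   \code{queries} (data frame like \code{\link{parse_mutation_list}}).
#' @export
parse_fasta_input <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("no FASTA records in ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1)
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence record in ", path, ": ",
         ids[which(nchar(seqs) == 0)[1]])
  }
  dup <- duplicated(ids)
  if (any(dup)) {
    for (id in unique(ids[dup])) {
      if (length(unique(seqs[ids == id])) > 1) {
        stop("duplicate FASTA id '", id, "' with differing sequences")
      }
    }
  }
  queries <- list()
  for (i in seq_along(ids)) {
    toks <- strsplit(headers[i], "\\s+")[[1]][-1]
    if (length(toks) == 0) {
      queries[[length(queries) + 1]] <- data.frame(
        input_id = ids[i], variant_text = "", tags = "",
        stringsAsFactors = FALSE)
    } else {
      for (tk in toks) {
        queries[[length(queries) + 1]] <- data.frame(
          input_id = ids[i], variant_text = tk, tags = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  list(sequences = stats::setNames(seqs[!dup], ids[!dup]),
       queries = do.call(rbind, queries))
}

#' Split proteins into ordered chunks
#'
#' @param ids vector of protein ids.
#' @param chunk_size proteins per chunk (default 100).
#' @return list of id vectors.
#' @export
chunk_input <- function(ids, chunk_size = 100) {
  stopifnot(chunk_size >= 1)
  if (length(ids) == 0) return(list())
  split(ids, ceiling(seq_along(ids) / chunk_size))
}

analysis_param_tag <- function(cfg) {
  sprintf("np%d_pr%g_dc%g_r%g_st%d", cfg$n_points, cfg$probe,
          cfg$dist_cutoff, cfg$radius, cfg$sep_threshold)
}

# per-entry structure analysis with in-memory memo + optional disk cache
get_structure_analysis <- function(entry_id, path, cfg, memo, log) {
  if (!is.null(memo[[entry_id]])) return(memo[[entry_id]])
  cache_file <- NULL
  if (identical(cfg$mode, "default") && !is.null(cfg$cache_dir)) {
    cache_file <- file.path(cfg$cache_dir,
                            paste0(entry_id, "__", analysis_param_tag(cfg),
                                   ".tsv"))
    if (file.exists(cache_file)) {
      feats <- utils::read.delim(cache_file, colClasses = NA,
                                 check.names = FALSE)
      feats$icode[is.na(feats$icode)] <- " "
      log(paste("analysis cache hit:", entry_id))
      memo[[entry_id]] <- feats
      return(feats)
    }
  }
  log(paste("analyzing structure:", entry_id))
  model <- parse_structure(path, entry_id)
  feats <- analyze_structure(model, n_points = cfg$n_points,
                             probe = cfg$probe,
                             dist_cutoff = cfg$dist_cutoff,
                             radius = cfg$radius,
                             sep_threshold = cfg$sep_threshold)
  if (!is.null(cache_file)) {
    utils::write.table(feats, cache_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  memo[[entry_id]] <- feats
  feats
}

# annotate one query sequence against the template library; returns the
# per-position aggregated table plus annotation metadata
annotate_sequence <- function(seq, index, cfg, memo, log = function(...) {}) {
  cand <- find_candidates(seq, index, k = cfg$k)
  annotations <- list()
  for (r in seq_len(nrow(cand))) {
    row <- index[index$entry_id == cand$entry_id[r] &
                 index$chain_id == cand$chain_id[r], , drop = FALSE][1, ]
    aln <- align_global_free_end(seq, row$sequence,
                                 gap_open = cfg$gap_open,
                                 gap_extend = cfg$gap_extend)
    if (!accept_annotation(aln$identity, cfg$identity_threshold)) next
    resnums <- as.integer(strsplit(row$resnums, ",")[[1]])
    icodes <- strsplit(row$icodes, ",")[[1]]
    icodes[icodes == ""] <- " "
    coverage <- alignment_coverage(aln)
    resolution <- suppressWarnings(as.numeric(row$resolution))
    q <- quality_score(aln$identity, coverage, resolution)
    pm <- map_positions(aln, resnums, icodes)
    feats <- get_structure_analysis(row$entry_id, row$path, cfg, memo, log)
    fsub <- feats[feats$chain == row$chain_id, , drop = FALSE]
    fkey <- paste(fsub$resnum, fsub$icode)
    pm$feat_row <- match(paste(pm$resnum, pm$icode), fkey)
    annotations[[length(annotations) + 1]] <- list(
      entry_id = row$entry_id, chain_id = row$chain_id,
      identity = aln$identity, coverage = coverage,
      resolution = resolution, quality = q,
      own_structure = aln$identity >= cfg$own_structure_identity,
      position_map = pm, features = fsub)
  }

  reg <- feature_registry()
  ereg <- evidence_registry()
  n <- nchar(seq)
  aa <- strsplit(seq, "")[[1]]
  rows <- vector("list", n)
  for (p in seq_len(n)) {
    frows <- list(); info <- list()
    for (ann in annotations) {
      hit <- ann$position_map[ann$position_map$qpos == p, , drop = FALSE]
      if (nrow(hit) == 0 || is.na(hit$feat_row[1])) next
      fr <- ann$features[hit$feat_row[1], , drop = FALSE]
      frows[[length(frows) + 1]] <- fr
      ntypes <- sum(vapply(.INTERFACE_TYPES, function(tp) {
        any(c(fr[[paste0("mainchain_", tp, "_degree")]],
              fr[[paste0("sidechain_", tp, "_degree")]]) > 0, na.rm = TRUE)
      }, logical(1)))
      info[[length(info) + 1]] <- data.frame(
        entry_id = ann$entry_id, chain_id = ann$chain_id,
        identity = ann$identity, coverage = ann$coverage,
        resolution = ann$resolution, quality = ann$quality,
        n_interaction_types = ntypes,
        resnum = fr$resnum, icode = fr$icode, resname = fr$resname,
        stringsAsFactors = FALSE)
    }
    nmapped <- length(frows)
    if (nmapped > 0) {
      frows <- do.call(rbind, frows)
      info <- do.call(rbind, info)
      agg <- aggregate_position_features(frows, info$quality, info$coverage)
      classes <- classify_position(agg, nmapped, cfg$rsa_threshold,
                                   cfg$degree_eps)
      ev <- evidence_features(info, frows, classes)
      refs <- select_recommended(info)
      ss_w <- c(H = agg[["ss_helix"]], E = agg[["ss_sheet"]],
                C = agg[["ss_coil"]])
      weighted_ss <- if (all(is.na(ss_w))) NA_character_ else
        names(ss_w)[which.max(ifelse(is.na(ss_w), -Inf, ss_w))]
      confidence <- mean(info$quality)
      mean_quality <- mean(info$quality)
    } else {
      agg <- stats::setNames(rep(NA_real_, length(reg)), reg)
      classes <- classify_position(agg, 0L)
      ev <- evidence_features(NULL, NULL, classes)
      refs <- list(max_identity = NULL, recommended = NULL)
      weighted_ss <- NA_character_
      confidence <- NA_real_
      mean_quality <- NA_real_
    }
    ref_cols <- function(ref, prefix) {
      if (is.null(ref)) {
        out <- list(NA_character_, NA_character_, NA_real_, NA_real_,
                    NA_real_)
      } else {
        out <- list(render_structure_ref(ref$entry_id, ref$chain_id),
                    render_residue_ref(ref$resnum, ref$icode, ref$resname),
                    ref$identity, ref$coverage, ref$resolution)
      }
      stats::setNames(out, paste0(prefix, c("_structure", "_residue",
                                            "_identity", "_coverage",
                                            "_resolution")))
    }
    base <- data.frame(position = p, wt_aa = aa[p],
                       n_structures = nmapped,
                       mean_quality = mean_quality,
                       confidence = confidence,
                       weighted_ss = weighted_ss,
                       stringsAsFactors = FALSE)
    base <- cbind(base, as.data.frame(classes, stringsAsFactors = FALSE),
                  as.data.frame(ref_cols(refs$recommended, "rec"),
                                stringsAsFactors = FALSE),
                  as.data.frame(ref_cols(refs$max_identity, "maxid"),
                                stringsAsFactors = FALSE),
                  as.data.frame(t(agg)), as.data.frame(t(ev)))
    rows[[p]] <- base
  }
  positions <- do.call(rbind, rows)
  rownames(positions) <- NULL
  list(positions = positions, annotations = annotations)
}

fmt_cell <- function(x) {
  if (is.numeric(x)) {
    out <- ifelse(is.na(x), "-", formatC(x, format = "g", digits = 6))
  } else {
    out <- ifelse(is.na(x) | x == "", "-", as.character(x))
  }
  out
}

write_tsv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_cell), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.CLASSIFICATION_COLUMNS <- c(
  "input_id", "primary_id", "position_or_variant", "wt_residue", "tags",
  "weighted_location", "weighted_mainchain_location",
  "weighted_sidechain_location", "weighted_rsa", "weighted_mainchain_rsa",
  "weighted_sidechain_rsa", "structural_class", "simple_class", "rin_class",
  "rin_simple_class", "interaction_profile", "weighted_secondary_structure",
  "classification_confidence", "n_mapped_structures",
  "recommended_structure", "recommended_residue", "recommended_identity",
  "recommended_coverage", "recommended_resolution",
  "max_identity_structure", "max_identity_residue", "max_identity",
  "max_identity_resolution")

classification_row <- function(input_id, primary_id, pos_label, wt, tags,
                               prow) {
  if (is.null(prow)) {
    out <- as.list(stats::setNames(rep("-", 28), .CLASSIFICATION_COLUMNS))
    out$input_id <- input_id; out$primary_id <- primary_id
    out$position_or_variant <- pos_label; out$wt_residue <- wt
    out$tags <- if (tags == "") "-" else tags
    out$structural_class <- "No structure"
    out$simple_class <- "No structure"
    out$rin_class <- "No structure"
    out$rin_simple_class <- "No structure"
    out$n_mapped_structures <- "0"
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  data.frame(
    input_id = input_id, primary_id = primary_id,
    position_or_variant = pos_label, wt_residue = wt,
    tags = if (tags == "") "-" else tags,
    weighted_location = prow$location,
    weighted_mainchain_location = prow$mainchain_location,
    weighted_sidechain_location = prow$sidechain_location,
    weighted_rsa = prow$rsa_all,
    weighted_mainchain_rsa = prow$rsa_mainchain,
    weighted_sidechain_rsa = prow$rsa_sidechain,
    structural_class = prow$structural_class,
    simple_class = prow$simple_class,
    rin_class = prow$rin_class,
    rin_simple_class = prow$rin_simple_class,
    interaction_profile = prow$interaction_profile,
    weighted_secondary_structure = prow$weighted_ss,
    classification_confidence = prow$confidence,
    n_mapped_structures = prow$n_structures,
    recommended_structure = prow$rec_structure,
    recommended_residue = prow$rec_residue,
    recommended_identity = prow$rec_identity,
    recommended_coverage = prow$rec_coverage,
    recommended_resolution = prow$rec_resolution,
    max_identity_structure = prow$maxid_structure,
    max_identity_residue = prow$maxid_residue,
    max_identity = prow$maxid_identity,
    max_identity_resolution = prow$maxid_resolution,
    stringsAsFactors = FALSE)
}

#' Run the full annotation pipeline
#'
#' @param job list with \code{sequences} (named character vector of query
#'   sequences) and \code{queries} (data frame \code{input_id},
#'   \code{variant_text}, \code{tags}); ids in \code{queries} without a
#'   sequence are looked up in the template library (ATOM-derived) and
#'   otherwise reported in \code{skipped_inputs.tsv}.
#' @param template_dir template library directory of PDB files.
#' @param outdir output directory (created).
#' @param config configuration list from \code{\link{default_config}}.
#' @return invisibly, a list with the output paths and run statistics.
#' @export
run_pipeline <- function(job, template_dir, outdir,
                         config = default_config()) {
  cfg <- config
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (identical(cfg$mode, "default") && is.null(cfg$cache_dir)) {
    cfg$cache_dir <- file.path(outdir, "cache")
  }
  if (identical(cfg$mode, "default")) {
    ok <- tryCatch({
      dir.create(cfg$cache_dir, showWarnings = FALSE, recursive = TRUE)
      file.access(cfg$cache_dir, 2) == 0
    }, error = function(e) FALSE)
    if (!ok) stop("cache directory not writable (", cfg$cache_dir,
                  "); consider lite mode")
  }
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)

  index <- build_template_index(template_dir)
  queries <- job$queries
  sequences <- job$sequences

  # resolve sequences for ids not given directly: template library lookup
  skipped <- NULL
  for (id in unique(queries$input_id)) {
    if (!is.null(sequences) && id %in% names(sequences)) next
    hit <- index[index$entry_id == id | paste0(index$entry_id, ":",
                                               index$chain_id) == id, ,
                 drop = FALSE]
    if (nrow(hit) > 0) {
      sequences[id] <- hit$sequence[1]
    } else {
      skipped <- rbind(skipped, data.frame(
        input_id = id, reason = "no sequence available",
        stringsAsFactors = FALSE))
      queries <- queries[queries$input_id != id, , drop = FALSE]
    }
  }

  # parse variants up front (validation against the sequence)
  queries$kind <- "whole"
  parsed <- vector("list", nrow(queries))
  drop_rows <- integer(0)
  for (i in seq_len(nrow(queries))) {
    vt <- queries$variant_text[i]
    if (vt == "") next
    pv <- tryCatch(parse_variant(vt, sequences[[queries$input_id[i]]]),
                   error = function(e) e)
    if (inherits(pv, "error")) {
      skipped <- rbind(skipped, data.frame(
        input_id = queries$input_id[i],
        reason = conditionMessage(pv), stringsAsFactors = FALSE))
      drop_rows <- c(drop_rows, i)
      next
    }
    parsed[[i]] <- pv
    queries$kind[i] <- pv$kind
  }
  if (length(drop_rows) > 0) {
    queries <- queries[-drop_rows, , drop = FALSE]
    parsed <- parsed[-drop_rows]
  }

  # never-compute-anything-twice: dedupe by sequence
  ids <- unique(queries$input_id)
  seq_of <- vapply(ids, function(id) sequences[[id]], character(1))
  primary_of <- stats::setNames(ids[match(seq_of, seq_of)], ids)

  work_seqs <- unique(seq_of)
  # mutant sequences for indels join the same analysis pool
  mut_seq_of <- list()
  for (i in seq_len(nrow(queries))) {
    v <- parsed[[i]]
    if (!is.null(v) && is_indel(v)) {
      ms <- apply_variant(sequences[[queries$input_id[i]]], v)
      mut_seq_of[[paste(queries$input_id[i], queries$variant_text[i])]] <- ms
      work_seqs <- c(work_seqs, ms)
    }
  }
  work_seqs <- unique(work_seqs)

  memo <- new.env(parent = emptyenv())
  results <- new.env(parent = emptyenv())
  chunks <- chunk_input(work_seqs, cfg$chunk_size)
  t0 <- Sys.time()
  for (ci in seq_along(chunks)) {
    chunk <- chunks[[ci]]
    log(sprintf("chunk %d/%d: %d sequence(s)", ci, length(chunks),
                length(chunk)))
    runner <- function(s) annotate_sequence(s, index, cfg, memo, log)
    res <- if (cfg$workers > 1 && .Platform$OS.type == "unix") {
      parallel::mclapply(chunk, runner, mc.cores = cfg$workers)
    } else {
      lapply(chunk, runner)
    }
    for (k in seq_along(chunk)) results[[chunk[k]]] <- res[[k]]
  }

  # assemble outputs
  reg <- feature_registry(); ereg <- evidence_registry()
  class_rows <- list(); feat_rows <- list(); indel_rows <- list()
  for (i in seq_len(nrow(queries))) {
    id <- queries$input_id[i]
    seq <- sequences[[id]]
    pos_tab <- results[[seq]]$positions
    v <- parsed[[i]]
    tags <- queries$tags[i]
    primary <- unname(primary_of[id])
    if (is.null(v)) {                      # whole-protein query
      for (p in seq_len(nrow(pos_tab))) {
        prow <- pos_tab[p, , drop = FALSE]
        class_rows[[length(class_rows) + 1]] <- classification_row(
          id, primary, as.character(p), prow$wt_aa, tags, prow)
        fv <- sav_feature_vector(
          stats::setNames(as.numeric(prow[1, reg]), reg),
          stats::setNames(as.numeric(prow[1, ereg]), ereg))
        feat_rows[[length(feat_rows) + 1]] <- cbind(
          data.frame(input_id = id, position_or_variant = as.character(p),
                     tags = if (tags == "") "-" else tags,
                     stringsAsFactors = FALSE),
          as.data.frame(t(fv)))
      }
    } else if (v$kind == "sav") {
      prow <- pos_tab[pos_tab$position == v$left, , drop = FALSE]
      class_rows[[length(class_rows) + 1]] <- classification_row(
        id, primary, v$text, v$wt_residues, tags, prow)
      fv <- sav_feature_vector(
        stats::setNames(as.numeric(prow[1, reg]), reg),
        stats::setNames(as.numeric(prow[1, ereg]), ereg))
      feat_rows[[length(feat_rows) + 1]] <- cbind(
        data.frame(input_id = id, position_or_variant = v$text,
                   tags = if (tags == "") "-" else tags,
                   stringsAsFactors = FALSE),
        as.data.frame(t(fv)))
    } else {                               # indel
      mut_seq <- mut_seq_of[[paste(id, queries$variant_text[i])]]
      mut_tab <- results[[mut_seq]]$positions
      dec <- decompose_indel(seq, mut_seq, v)
      iv <- aggregate_indel_features(pos_tab, mut_tab, dec)
      indel_rows[[length(indel_rows) + 1]] <- cbind(
        data.frame(input_id = id, position_or_variant = v$text,
                   tags = if (tags == "") "-" else tags,
                   stringsAsFactors = FALSE),
        as.data.frame(t(iv)))
      prow <- pos_tab[pos_tab$position == v$left, , drop = FALSE]
      if (nrow(prow) == 0) prow <- NULL
      class_rows[[length(class_rows) + 1]] <- classification_row(
        id, primary, v$text,
        if (is.na(v$wt_residues) || v$wt_residues == "") "-"
        else v$wt_residues,
        tags, prow)
    }
  }

  paths <- list(
    classification = file.path(outdir, "classification.tsv"),
    features = file.path(outdir, "features.tsv"),
    indel_features = file.path(outdir, "indel_features.tsv"),
    manifest = file.path(outdir, "feature_manifest.tsv"),
    tag_summary = file.path(outdir, "tag_summary.tsv"),
    skipped = file.path(outdir, "skipped_inputs.tsv"),
    log = file.path(outdir, "run.log"))

  class_tab <- if (length(class_rows) > 0) do.call(rbind, class_rows) else
    stats::setNames(as.data.frame(matrix(character(0), 0, 28),
                                  stringsAsFactors = FALSE),
                    .CLASSIFICATION_COLUMNS)
  stopifnot(identical(names(class_tab), .CLASSIFICATION_COLUMNS))
  write_tsv(class_tab, paths$classification)

  feat_tab <- if (length(feat_rows) > 0) do.call(rbind, feat_rows) else
    stats::setNames(
      as.data.frame(matrix(character(0), 0, 3 + 123)),
      c("input_id", "position_or_variant", "tags", reg, ereg))
  write_tsv(feat_tab, paths$features)

  indel_tab <- if (length(indel_rows) > 0) do.call(rbind, indel_rows) else
    stats::setNames(
      as.data.frame(matrix(character(0), 0, 3 + 600)),
      c("input_id", "position_or_variant", "tags", indel_feature_registry()))
  write_tsv(indel_tab, paths$indel_features)

  manifest <- rbind(
    data.frame(table = "features.tsv", index = seq_len(123),
               column = c(reg, ereg),
               kind = c(rep("aggregatable", 100), rep("evidence", 23)),
               stringsAsFactors = FALSE),
    data.frame(table = "indel_features.tsv", index = seq_len(600),
               column = indel_feature_registry(),
               kind = rep(.INDEL_REGIONS, each = 100),
               stringsAsFactors = FALSE))
  write_tsv(manifest, paths$manifest)

  write_tsv(tag_summary(class_tab), paths$tag_summary)

  if (is.null(skipped)) {
    skipped <- data.frame(input_id = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  }
  write_tsv(skipped, paths$skipped)

  log(sprintf("done: %d classification row(s) in %.1f s",
              nrow(class_tab), as.numeric(Sys.time() - t0, units = "secs")))
  writeLines(log_lines, paths$log)
  invisible(list(paths = paths, outdir = outdir,
                 n_analyzed = sum(grepl("^analyzing structure",
                                        log_lines)),
                 n_cache_hits = sum(grepl("^analysis cache hit",
                                          log_lines)),
                 classification = class_tab))
}

#' Per-tag summary statistics
#'
#' @param class_tab the classification table.
#' @return data frame: one row per (tag, simple class) with position counts
#'   plus per-tag mean/median weighted RSA.
#' @export
tag_summary <- function(class_tab) {
  rows <- list()
  tags_col <- class_tab$tags
  for (tag in sort(unique(unlist(strsplit(tags_col[tags_col != "-"],
                                          ","))))) {
    sel <- vapply(strsplit(tags_col, ","), function(x) tag %in% x,
                  logical(1))
    sub <- class_tab[sel, , drop = FALSE]
    rsa <- suppressWarnings(as.numeric(sub$weighted_rsa))
    for (cl in sort(unique(sub$simple_class))) {
      rows[[length(rows) + 1]] <- data.frame(
        tag = tag, simple_class = cl, n = sum(sub$simple_class == cl),
        n_tagged = nrow(sub),
        mean_weighted_rsa = mean(rsa, na.rm = TRUE),
        median_weighted_rsa = stats::median(rsa, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(tag = character(0), simple_class = character(0),
                      n = integer(0), n_tagged = integer(0),
                      mean_weighted_rsa = numeric(0),
                      median_weighted_rsa = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
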
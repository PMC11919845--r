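#' @title File formats: pair tables, FASTA, contact maps, checkpoints
#'
#' @description
#' Tab-separated tables are the canonical tabular format (SMILES may contain
#' commas in extended notation). Contact maps and residue embeddings travel
#' as dense whitespace-delimited numeric matrices, one file per target named
#' `<target_id>.txt`. Model checkpoints are JSON containers holding the
#' configuration, all parameter arrays and the training history.
#'
#' @name io
NULL

#' Read a drug-target pair table
#'
#' Expects a TSV with header columns `drug_id`, `target_id`, `label` (an
#' optional `split` column is preserved). Duplicate (drug, target) rows and
#' malformed labels are rejected with the offending line numbers.
#'
#' @param path file path
#' @return validated data frame
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("pair table not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("drug_id", "target_id", "label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("pair table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- which(!nzchar(df$drug_id) | !nzchar(df$target_id))
  if (length(bad) > 0L) {
    stop("empty drug/target id at line(s) ", paste(line[bad], collapse = ", "),
         " of ", path)
  }
  if (!all(df$label %in% c("0", "1"))) {
    bad <- which(!df$label %in% c("0", "1"))
    stop("label must be 0 or 1; offending line(s) ",
         paste(head(line[bad], 10L), collapse = ", "), " of ", path)
  }
  key <- paste(df$drug_id, df$target_id, sep = "\t")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    where <- line[key == d]
    stop("duplicate pair '", gsub("\t", " / ", d), "' at lines ",
         paste(where, collapse = " and "), " of ", path)
  }
  df$label <- as.integer(df$label)
  df
}

#' Write a pair table as TSV
#' @param pairs data frame
#' @param path destination
#' @export
write_pairs <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read protein sequences from a FASTA file
#'
#' Record ids are the first whitespace-delimited header token; sequences are
#' upper-cased and letters outside the 20-residue alphabet map to `X` (a
#' message reports how many were mapped).
#'
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("no records in FASTA file ", path)
  seqs <- toupper(as.character(ss))
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  if (any(!nzchar(seqs))) {
    stop("empty sequence record in ", path, ": ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  n_bad <- sum(vapply(strsplit(seqs, ""), function(ch) sum(!ch %in% AA_ALPHABET),
                      numeric(1)))
  if (n_bad > 0) {
    message(n_bad, " non-standard residue letter(s) mapped to X while reading ", path)
    seqs <- vapply(strsplit(seqs, ""), function(ch) {
      ch[!ch %in% AA_ALPHABET] <- "X"
      paste(ch, collapse = "")
    }, character(1))
  }
  setNames(seqs, ids)
}

#' Read a SMILES table
#'
#' Accepts a TSV with header columns `drug_id` and `smiles`, or a headerless
#' list with one SMILES per line, optionally followed by a tab-separated id.
#'
#' @param path file path
#' @return data frame with `drug_id`, `smiles`
#' @export
read_smiles_table <- function(path) {
  if (!file.exists(path)) stop("SMILES file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("smiles", tolower(first))) {
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                     colClasses = "character")
    if (!all(c("drug_id", "smiles") %in% names(df))) {
      stop("SMILES table ", path, " needs columns drug_id and smiles")
    }
    return(df[, c("drug_id", "smiles")])
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  data.frame(
    drug_id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1L) parts[[i]][2L] else paste0("drug_", i)
    }, character(1)),
    smiles = vapply(parts, `[[`, character(1), 1L),
    stringsAsFactors = FALSE
  )
}

#' Read a dense contact-probability matrix
#'
#' Whitespace- or comma-delimited square numeric matrix.
#'
#' @param path file path
#' @return numeric matrix
#' @export
read_contact_map <- function(path) {
  if (!file.exists(path)) stop("contact map not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(strsplit(trimws(lines), "[,[:space:]]+"), as.numeric)
  M <- do.call(rbind, rows)
  if (nrow(M) != ncol(M)) {
    stop("contact map ", path, " is not square (", nrow(M), "x", ncol(M), ")")
  }
  M
}

#' Write a contact map
#' @param M matrix
#' @param path destination
#' @export
write_contact_map <- function(M, path) {
  write.table(format(M, digits = 6), path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Load protein records from FASTA plus a contact-map directory
#'
#' @param fasta_path FASTA file of target sequences
#' @param contacts_dir directory of `<target_id>.txt` contact maps, or `NULL`
#' @param require_contacts error (rather than proceed without a graph) when a
#'   map is missing — prevents silently degrading to sequence-only encoding
#' @param max_seq_len truncation length
#' @return named list of [protein_record()]
#' @export
load_protein_records <- function(fasta_path, contacts_dir = NULL,
                                 require_contacts = !is.null(contacts_dir),
                                 max_seq_len = 1000L) {
  seqs <- read_fasta(fasta_path)
  records <- lapply(names(seqs), function(id) {
    M <- NULL
    if (!is.null(contacts_dir)) {
      f <- file.path(contacts_dir, paste0(id, ".txt"))
      if (file.exists(f)) {
        M <- read_contact_map(f)
      } else if (require_contacts) {
        stop("no contact map for target '", id, "' in ", contacts_dir,
             " (expected ", f, ")")
      }
    }
    protein_record(id, seqs[[id]], contact_map = M, max_seq_len = max_seq_len)
  })
  setNames(records, names(seqs))
}

# ---- checkpoints ------------------------------------------------------------

#' Save a model checkpoint
#'
#' JSON container with the configuration, every parameter array at full
#' precision, and the training history.
#'
#' @param model a `dti_model`
#' @param path destination (.json)
#' @export
save_model <- function(model, path) {
  payload <- list(
    format = "blockdti-checkpoint-1",
    cfg = unclass_deep(model$cfg),
    params = model$params,
    history = if (is.null(model$history)) NULL else as.list(model$history),
    best_epoch = model$best_epoch
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

#' Load a model checkpoint
#'
#' @param path checkpoint written by [save_model()]
#' @return a `dti_model`
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  ck <- jsonlite::read_json(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  if (!identical(ck$format, "blockdti-checkpoint-1")) {
    stop(path, " is not a recognized checkpoint")
  }
  cfg <- dti_model_config(
    channels = ck$cfg$channels, n_blocks = ck$cfg$drug$n_blocks,
    n_layers = ck$cfg$drug$n_layers, gnn_type = ck$cfg$drug$gnn_type,
    enhancement_scale = ck$cfg$drug$enhancement_scale,
    dropout = ck$cfg$dropout, windows = ck$cfg$target$windows,
    contact_threshold = ck$cfg$target$contact_threshold,
    use_graph = ck$cfg$target$use_graph,
    max_seq_len = ck$cfg$target$max_seq_len,
    head_hidden = ck$cfg$head_hidden
  )
  params <- restore_arrays(ck$params)
  history <- if (is.null(ck$history)) NULL else as.data.frame(ck$history)
  structure(list(cfg = cfg, params = params, history = history,
                 best_epoch = ck$best_epoch),
            class = "dti_model")
}

# jsonlite round-trips numeric vectors/matrices faithfully; biases of length
# one come back as scalars, which R treats as length-1 vectors, so no special
# casing is needed beyond recursing into lists.
restore_arrays <- function(x) {
  if (is.list(x)) return(lapply(x, restore_arrays))
  x
}

# ---- run configuration ------------------------------------------------------

#' Read a run configuration file
#'
#' YAML with up to four sections: `model`, `train`, `split`, `data`. Keys
#' must match the arguments of [dti_model_config()], [train_config()] and
#' [split_spec()]; unknown sections or keys are rejected.
#'
#' @param path YAML file (or `NULL` for all defaults)
#' @return list with `model`, `train`, `split` argument lists and `data`
#'   paths
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  allowed <- list(
    model = names(formals(dti_model_config)),
    train = names(formals(train_config)),
    split = names(formals(split_spec)),
    data = c("pairs", "smiles", "fasta", "contacts", "out_dir")
  )
  bad_sec <- setdiff(names(raw), names(allowed))
  if (length(bad_sec) > 0L) {
    stop("unknown config section(s): ", paste(bad_sec, collapse = ", "))
  }
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), allowed[[sec]])
    if (length(bad) > 0L) {
      stop("unknown key(s) in config section '", sec, "': ",
           paste(bad, collapse = ", "))
    }
  }
  list(model = raw$model %||% list(), train = raw$train %||% list(),
       split = raw$split %||% list(), data = raw$data %||% list())
}
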
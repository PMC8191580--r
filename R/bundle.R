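BUNDLE_VERSION <- "1"

write_num_matrix <- function(m, path) {
  m <- as.matrix(m)
  lines <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, path)
}

read_num_matrix <- function(path) {
  lines <- readLines(path)
  do.call(rbind, lapply(strsplit(lines, "\t", fixed = TRUE), as.numeric))
}

model_param_files <- function(model, side) {
  L <- length(model$W)
  parts <- expand.grid(part = c("W", "b", "Wd", "bd"), layer = seq_len(L),
                       stringsAsFactors = FALSE)
  sprintf("%s_%s%d.tsv", side, parts$part, parts$layer)
}

#' Save a trained decomposition bundle to a directory
#'
#' The bundle is stored as plain text: one TSV per weight matrix / bias
#' vector at full double precision (round-trips exactly), plus a
#' `metadata.json` holding the gene panels, selected node indices, sign
#' conventions, training configuration, and per-file checksums that
#' guard against truncation.
#'
#' @param bundle [decompose_cohort()] result.
#' @param dir target directory (created; must be empty or absent).
#' @return `dir`, invisibly.
#' @export
save_model_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "decomp_bundle"))
  if (!isTRUE(bundle$te$model$trained) || !isTRUE(bundle$ti$model$trained))
    stop("bundle models are untrained; refusing to save")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  checksums <- list()
  for (side in c("te", "ti")) {
    model <- bundle[[side]]$model
    L <- length(model$W)
    for (l in seq_len(L)) {
      for (part in c("W", "b", "Wd", "bd")) {
        fn <- sprintf("%s_%s%d.tsv", side, part, l)
        val <- model[[part]][[l]]
        write_num_matrix(if (is.matrix(val)) val else matrix(val, nrow = 1L),
                         file.path(dir, fn))
        checksums[[fn]] <- sum(val)
      }
    }
  }
  side_meta <- function(side) {
    m <- bundle[[side]]$model
    list(panel = bundle[[side]]$panel,
         node_index = bundle[[side]]$def$node_index,
         sign = bundle[[side]]$def$sign,
         compartment = bundle[[side]]$def$compartment,
         selection_stats = bundle[[side]]$def$selection_stats,
         gene_weights = as.list(bundle[[side]]$gene_weights),
         layer_sizes = m$layer_sizes,
         linear_bottleneck = m$linear_bottleneck,
         seed = m$seed)
  }
  meta <- list(version = BUNDLE_VERSION,
               config = unclass(bundle$config),
               selection = list(gh_genes = bundle$selection$gh_genes,
                                gl_genes = bundle$selection$gl_genes,
                                k = bundle$selection$k),
               te = side_meta("te"), ti = side_meta("ti"),
               checksums = checksums)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a decomposition bundle saved by [save_model_bundle()]
#'
#' Verifies the format version and every file checksum; a truncated or
#' corrupted file is a hard error. The reloaded bundle reproduces
#' encoder outputs to within 1e-12 elementwise.
#'
#' @param dir bundle directory.
#' @return `decomp_bundle` list.
#' @export
load_model_bundle <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path)) stop("not a model bundle: ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(as.character(meta$version), BUNDLE_VERSION))
    stop(sprintf("bundle version %s not supported (expected %s)",
                 meta$version, BUNDLE_VERSION))
  load_side <- function(side) {
    sm <- meta[[side]]
    sizes <- as.integer(sm$layer_sizes)
    L <- length(sizes) - 1L
    dec_sizes <- rev(sizes)
    model <- list(W = vector("list", L), b = vector("list", L),
                  Wd = vector("list", L), bd = vector("list", L),
                  layer_sizes = sizes,
                  linear_bottleneck = isTRUE(sm$linear_bottleneck),
                  trained = TRUE, seed = as.integer(sm$seed))
    for (l in seq_len(L)) {
      for (part in c("W", "b", "Wd", "bd")) {
        fn <- sprintf("%s_%s%d.tsv", side, part, l)
        path <- file.path(dir, fn)
        if (!file.exists(path)) stop("bundle file missing: ", fn)
        m <- read_num_matrix(path)
        if (anyNA(m)) stop("corrupted bundle file (non-numeric): ", fn)
        expected <- meta$checksums[[fn]]
        if (abs(sum(m) - expected) > 1e-8 * max(1, abs(expected)))
          stop("checksum mismatch (truncated or corrupted file): ", fn)
        exp_dim <- switch(part,
          W = c(sizes[[l]], sizes[[l + 1L]]),
          b = c(1L, sizes[[l + 1L]]),
          Wd = c(dec_sizes[[l]], dec_sizes[[l + 1L]]),
          bd = c(1L, dec_sizes[[l + 1L]]))
        if (!identical(dim(m), as.integer(exp_dim)))
          stop("unexpected shape in bundle file: ", fn)
        model[[part]][[l]] <- if (part %in% c("b", "bd")) as.numeric(m) else m
      }
    }
    class(model) <- "autoencoder"
    gw <- unlist(sm$gene_weights)
    def <- structure(list(compartment = sm$compartment,
                          node_index = as.integer(sm$node_index),
                          selection_stats = as.data.frame(sm$selection_stats),
                          sign = as.numeric(sm$sign)),
                     class = "signature_definition")
    list(model = model, panel = as.character(sm$panel), def = def,
         gene_weights = gw)
  }
  cfg <- meta$config
  config <- training_config(lambda = cfg$lambda,
                            learning_rate = cfg$learning_rate,
                            momentum = cfg$momentum, epochs = cfg$epochs,
                            batch_size = cfg$batch_size,
                            clip_norm = if (is.null(cfg$clip_norm)) 5
                                        else cfg$clip_norm,
                            seed = cfg$seed,
                            hidden = as.integer(cfg$hidden),
                            bottleneck = cfg$bottleneck,
                            linear_bottleneck = isTRUE(cfg$linear_bottleneck))
  structure(list(te = load_side("te"), ti = load_side("ti"),
                 selection = structure(
                   list(gh_genes = as.character(meta$selection$gh_genes),
                        gl_genes = as.character(meta$selection$gl_genes),
                        k = as.integer(meta$selection$k)),
                   class = "gene_selection"),
                 config = config),
            class = "decomp_bundle")
}
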
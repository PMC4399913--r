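# Stage orchestration: run one pipeline stage from a validated config,
# writing outputs plus a metadata sidecar (parameters, seed, input digests)
# so every artifact is reproducible from its sidecar alone.

#' Run one pipeline stage
#'
#' Dispatches a stage of the analysis pipeline from a YAML config (path or
#' pre-parsed list). Outputs are written to `config$out_dir`; each artifact
#' gets a `<name>.meta.json` sidecar with the stage, parameters, seed and
#' md5 digests of the inputs. On any error partial outputs are removed and
#' the error is re-thrown, so a caller (or the command-line wrapper) can
#' exit non-zero.
#'
#' Supported stages: `simulate` (JTT alignment on a tree), `tree` (NJ or
#' ML), `bootstrap`, `nnet` (NeighborNet from an alignment or distance
#' TSV), `pockets`, `sodium_site`, `volumes`, `repertoire`,
#' `compare_splits`.
#'
#' @param config YAML path or named list; must contain `out_dir` and the
#'   stage-specific fields documented in the package vignette.
#' @param stage stage name (see above).
#' @return Invisible character vector of artifact paths.
#' @export
run_stage <- function(config,
                      stage = c("simulate", "tree", "bootstrap", "nnet",
                                "pockets", "sodium_site", "volumes",
                                "repertoire", "compare_splits")) {
  stage <- match.arg(stage)
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$out_dir)) stop("config must define out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  need_input <- function(path, what) {
    if (is.null(path) || !file.exists(path))
      stop("missing input for ", what, ": ",
           if (is.null(path)) "(not set)" else path)
    inputs <<- c(inputs, path)
    path
  }
  written <- character(0)
  out_path <- function(name) {
    p <- file.path(cfg$out_dir, name)
    written <<- c(written, p)
    p
  }
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)

  run <- function() {
    switch(stage,
      simulate = {
        tree <- if (!is.null(cfg$tree_file))
          ape::read.tree(need_input(cfg$tree_file, "tree"))
        else as_phylo_tree(cfg$tree)
        aln <- simulate_alignment(tree, length = cfg$length %||% 500,
                                  seed = seed)
        write_fasta(aln, out_path("alignment.fasta"))
        ape::write.tree(tree, out_path("true_tree.nwk"))
      },
      tree = {
        aln <- read_fasta(need_input(cfg$alignment, "alignment"))
        method <- cfg$method %||% "nj"
        tr <- if (method == "nj")
          neighbor_joining(dist_matrix(aln, method = cfg$distance %||% "p"))
        else ml_tree(aln, schedule = cfg$schedule %||% "both")$tree
        ape::write.tree(tr, out_path("tree.nwk"))
      },
      bootstrap = {
        aln <- read_fasta(need_input(cfg$alignment, "alignment"))
        bs <- bootstrap_support(aln, n_replicates = cfg$replicates %||% 1000,
                                seed = seed,
                                builder = cfg$builder %||% "nj",
                                distance = cfg$distance %||% "p")
        ape::write.tree(annotate_support(bs), out_path("tree_support.nwk"))
        utils::write.table(bs$support, out_path("support.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      },
      nnet = {
        d <- if (!is.null(cfg$distances))
          read_dist_tsv(need_input(cfg$distances, "distances"))
        else dist_matrix(read_fasta(need_input(cfg$alignment, "alignment")),
                         method = cfg$distance %||% "p")
        ss <- neighbor_net(d, eps = cfg$eps %||% 1e-9)
        write_nexus_splits(ss, out_path("network.nex"))
        write_splits_tsv(ss, out_path("splits.tsv"))
      },
      pockets = ,
      sodium_site = {
        arts <- character(0)
        sets <- list()
        for (rc in cfg$receptors) {
          at <- read_structure(need_input(rc$pdb, rc$name))
          spans <- as.data.frame(do.call(rbind, lapply(rc$helix_spans,
                                                       as.data.frame)))
          anchors <- unlist(rc$anchors)
          seqv <- structure_sequence(at)
          bw <- assign_bw_numbers(seqv$aa, spans, anchors)
          sets[[rc$name]] <- if (stage == "pockets")
            extract_ligand_contacts(at, rc$ligand %||% "LIG",
                                    cutoff = cfg$cutoff %||% 4.0,
                                    bw_map = bw, helix_spans = spans)
          else
            extract_sodium_site(at, cutoff = cfg$cutoff %||% 4.0,
                                bw_map = bw, helix_spans = spans)
        }
        prof <- build_pocket_profiles(sets)
        write_pocket_profiles(prof, out_path("profiles.fasta"),
                              out_path("positions.tsv"))
        write_dist_tsv(pocket_dist(prof, method = cfg$distance %||% "p"),
                       out_path("profile_distances.tsv"))
      },
      volumes = {
        structures <- lapply(cfg$pdbs, function(p)
          read_structure(need_input(p, "structure")))
        grid <- ligand_volume(structures,
                              ligand_resid = cfg$ligand %||% "LIG",
                              atom_radius = cfg$atom_radius %||% 1.7,
                              spacing = cfg$grid_spacing %||% 0.5)
        jsonlite::write_json(list(voxels = nrow(grid$indices),
                                  spacing = grid$spacing,
                                  volume_A3 = grid_volume(grid)),
                             out_path("volume.json"), auto_unbox = TRUE)
      },
      repertoire = {
        seqs <- read_fasta(need_input(cfg$sequences, "sequences"))
        res <- run_repertoire(seqs, cfg$crystal_names,
                              max_len = cfg$max_len %||% 1500,
                              max_groups = cfg$max_groups %||% 7,
                              distance = cfg$distance %||% "p",
                              realign = cfg$realign %||% TRUE)
        utils::write.table(res$table, out_path("groups.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(res$removed, out_path("removed.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        for (g in res$groups)
          write_fasta(g$members, out_path(paste0(g$group_id, ".fasta")))
      },
      compare_splits = {
        s1 <- read_splits_tsv(need_input(cfg$splits1, "splits1"))
        s2 <- read_splits_tsv(need_input(cfg$splits2, "splits2"))
        cmp <- compare_split_systems(s1, s2)
        utils::write.table(
          data.frame(metric = c("jaccard", "n_shared", "n_only1", "n_only2"),
                     value = c(cmp$jaccard, length(cmp$shared),
                               length(cmp$only1), length(cmp$only2))),
          out_path("comparison.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
      })
    invisible(NULL)
  }

  ok <- FALSE
  tryCatch({
    run()
    ok <- TRUE
  }, finally = {
    if (!ok) unlink(written)
  })
  meta <- list(stage = stage, seed = seed,
               parameters = cfg[setdiff(names(cfg), "out_dir")],
               inputs = as.list(tools::md5sum(unique(inputs))),
               package = as.character(utils::packageVersion("gpcrnet")))
  for (p in written)
    jsonlite::write_json(meta, paste0(p, ".meta.json"), auto_unbox = TRUE,
                         pretty = TRUE)
  invisible(written)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one-letter sequence + resno table from an atom table (CA records)
structure_sequence <- function(at) {
  ca <- at[at$type == "ATOM" & at$elety == "CA", ]
  ca <- ca[order(ca$resno), ]
  aa <- THREE_TO_ONE[ca$resid]
  aa[is.na(aa)] <- "X"
  list(aa = unname(aa), resno = ca$resno)
}

# splits TSV with a taxa header comment, so systems can be reloaded
write_splits_tsv <- function(ss, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# taxa: ", paste(ss$taxa, collapse = ",")), con)
  writeLines(paste0("# cycle: ", paste(ss$ordering, collapse = ",")), con)
  utils::write.table(ss$splits, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_splits_tsv <- function(path) {
  lines <- readLines(path)
  taxa <- strsplit(sub("^# taxa: ", "", lines[1]), ",")[[1]]
  cycle <- strsplit(sub("^# cycle: ", "", lines[2]), ",")[[1]]
  tab <- utils::read.delim(text = lines[-(1:2)], stringsAsFactors = FALSE)
  new_split_system(taxa, cycle, tab)
}
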
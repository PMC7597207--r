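# Input/output: emitter export (JSONL / CSV), experiment configuration
# files (YAML/JSON), fixture generation, and optional FASTA sequence import.

#' Write an emitted time series as JSON Lines
#'
#' One JSON object per emission: `time` plus the flattened variable paths.
#'
#' @param emitted Data frame from [run_experiment()]`$emitted`.
#' @param path Output file.
#' @export
write_emitted_jsonl <- function(emitted, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(emitted))) {
    row <- as.list(emitted[i, , drop = FALSE])
    row <- row[!vapply(row, function(v) is.na(v), TRUE)]
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Write an emitted time series as CSV
#'
#' @param emitted Data frame from [run_experiment()]`$emitted`.
#' @param path Output file.
#' @export
write_emitted_csv <- function(emitted, path) {
  utils::write.csv(emitted, path, row.names = FALSE)
  invisible(path)
}

#' Export a field snapshot as a CSV matrix
#'
#' @param field A `cs_field`.
#' @param species Species name.
#' @param path Output file.
#' @export
write_field_csv <- function(field, species, path) {
  utils::write.table(field$grids[[species]], path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load an experiment configuration file
#'
#' YAML or JSON with at least `experiment`; remaining keys are passed to the
#' matching builder (see [build_experiment()]).
#'
#' @param path Config file (.yaml/.yml/.json).
#' @return Config list.
#' @export
load_experiment_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Generate packaged fixture files
#'
#' Writes deterministic, schema-valid JSON fixtures:
#' \describe{
#'   \item{toy_metabolism}{The glucose/lactose toy network.}
#'   \item{toy_chromosome}{A minimal lac-like operon chromosome.}
#'   \item{flagellar_network}{The seven-operon flagellar regulon with its
#'     complexation chain (synthetic sequences).}
#'   \item{gradient_env}{Exponential-gradient environment parameters.}
#' }
#'
#' @param kind Fixture kind.
#' @param out_dir Output directory.
#' @param seed Seed for synthetic sequences.
#' @param params Optional parameter overrides.
#' @return The written file path.
#' @export
generate_fixtures <- function(kind = c("toy_metabolism", "toy_chromosome",
                                       "flagellar_network", "gradient_env"),
                              out_dir = ".", seed = 7, params = list()) {
  kind <- match.arg(kind)
  path <- file.path(out_dir, paste0(kind, ".json"))
  obj <- switch(kind,
    toy_metabolism = {
      net <- toy_metabolism()
      list(reactions = lapply(net$reactions, as.list),
           bounds = net$bounds,
           objective = as.list(net$objective),
           exchange_reactions = net$exchange_reactions,
           exchange_species = as.list(net$exchange_species),
           molecular_weights = as.list(net$molecular_weights))
    },
    toy_chromosome = toy_chromosome_fixture(seed),
    flagellar_network = {
      fx <- flagellar_network(seed)
      list(operons = fx$chromosome$operons,
           complexation = lapply(fx$complexation$reactions, function(r) {
             list(stoich = as.list(r$stoich), rate = r$rate)
           }),
           polymerases = fx$polymerases)
    },
    gradient_env = utils::modifyList(
      list(shape = "exponential", nx = 20, ny = 60, bin_size = 20,
           c0 = 0.02, lambda = 150, species = "ligand"), params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# a minimal lac-like operon: one promoter repressed by LacI (relieved when
# the inducer signal exceeds the site threshold), three genes
toy_chromosome_fixture <- function(seed = 7) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  genes <- list(lacZ = list(aa_seq = synthetic_protein(80), rbs_affinity = 0.2),
                lacY = list(aa_seq = synthetic_protein(60), rbs_affinity = 0.2),
                lacA = list(aa_seq = synthetic_protein(40), rbs_affinity = 0.1))
  nt <- sum(vapply(genes, function(g) 3 * nchar(g$aa_seq), 0)) + 30
  list(operons = list(lac = list(
    sequence = synthetic_dna(nt),
    promoter = list(basal = 0.05,
                    sites = list(list(tf = "LacI", role = "repressor",
                                      threshold = 10, weight = 0))),
    genes = genes)))
}

#' Load a chromosome configuration from fixture JSON
#'
#' @param path JSON written by [generate_fixtures()] (kinds
#'   `toy_chromosome` or `flagellar_network`).
#' @return A [chromosome_config()]; for a flagellar-network fixture, a list
#'   with `chromosome`, `complexation`, `polymerases`.
#' @export
load_chromosome <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  chrom <- chromosome_config(lapply(j$operons, function(o) {
    o$promoter$basal <- o$promoter$basal %||% 0
    o
  }))
  if (is.null(j$complexation)) return(chrom)
  cxn <- complexation_network(lapply(j$complexation, function(r) {
    list(stoich = unlist(r$stoich), rate = r$rate)
  }))
  list(chromosome = chrom, complexation = cxn,
       polymerases = lapply(j$polymerases, as.numeric))
}

#' Import operon sequences from a FASTA file
#'
#' Replaces (or adds) operon sequences by matching FASTA record names to
#' operon ids. Requires the Biostrings package.
#'
#' @param chromosome A [chromosome_config()].
#' @param fasta_path FASTA file.
#' @return The chromosome with sequences substituted.
#' @export
import_sequences_fasta <- function(chromosome, fasta_path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for FASTA import")
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  for (nm in names(seqs)) {
    if (!is.null(chromosome$operons[[nm]])) {
      chromosome$operons[[nm]]$sequence <- as.character(seqs[[nm]])
      chromosome$operons[[nm]]$terminator <- nchar(chromosome$operons[[nm]]$sequence)
    }
  }
  chromosome
}
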
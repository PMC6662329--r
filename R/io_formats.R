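# Input formats and domain containers.
#
# All downstream statistics consume the containers built here:
# phased_alignment (two haplotype sequences per diploid individual),
# codon_partition (PBR vs non-PBR codon indices), msat_dataset (diploid
# multiallelic genotypes with an explicit missing mask) and the validated
# individual metadata table.

#' Construct a phased haplotype alignment
#'
#' A phased alignment holds the two resolved haplotype sequences of each
#' diploid individual, all of equal length and in a known reading frame.
#'
#' @param sequences character vector of nucleotide strings (A/C/G/T/N/-),
#'   all the same length.
#' @param individual_id character vector, one id per sequence; every id must
#'   occur exactly twice.
#' @param haplotype_index integer vector of 1/2 labelling the two phases of
#'   each individual.
#' @param population character vector of population labels per sequence (or
#'   a single label recycled to all sequences).
#' @param frame_offset 0-based position of the first complete codon.
#' @return an object of class `phased_alignment` with elements `sequences`,
#'   `individual_id`, `haplotype_index`, `population`, `frame_offset` and the
#'   character matrix `mat` (haplotypes x sites).
#' @export
phased_alignment <- function(sequences, individual_id, haplotype_index,
                             population, frame_offset = 0L) {
  sequences <- toupper(as.character(sequences))
  n <- length(sequences)
  if (n == 0L) stop("alignment is empty", call. = FALSE)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("format error: sequences have unequal lengths (",
         paste(sort(unique(lens)), collapse = ", "), ")", call. = FALSE)
  }
  L <- lens[[1L]]
  if (length(population) == 1L) population <- rep(population, n)
  stopifnot(length(individual_id) == n, length(haplotype_index) == n,
            length(population) == n)
  haplotype_index <- as.integer(haplotype_index)
  if (!all(haplotype_index %in% c(1L, 2L))) {
    stop("haplotype_index must be 1 or 2", call. = FALSE)
  }
  mat <- matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
                nrow = n, byrow = TRUE)
  bad <- setdiff(unique(as.vector(mat)), DNA_ALPHABET)
  if (length(bad) > 0L) {
    stop("alphabet error: illegal character(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- table(individual_id)
  odd <- names(counts)[counts != 2L]
  if (length(odd) > 0L) {
    stop("pairing error: individual(s) without exactly 2 haplotypes: ",
         paste(odd, collapse = ", "), call. = FALSE)
  }
  per_ind <- tapply(haplotype_index, individual_id, function(h) sort(h))
  if (!all(vapply(per_ind, function(h) identical(h, c(1L, 2L)), logical(1)))) {
    stop("pairing error: each individual needs haplotype indices 1 and 2",
         call. = FALSE)
  }
  frame_offset <- as.integer(frame_offset)
  if (L - frame_offset < 3L) {
    stop("alignment too short for a single codon after frame_offset",
         call. = FALSE)
  }
  structure(
    list(sequences = sequences, individual_id = as.character(individual_id),
         haplotype_index = haplotype_index, population = as.character(population),
         frame_offset = frame_offset, mat = mat),
    class = "phased_alignment")
}

#' @export
print.phased_alignment <- function(x, ...) {
  cat("phased_alignment:", length(x$sequences), "haplotypes (",
      length(unique(x$individual_id)), "individuals ),",
      nchar(x$sequences[[1L]]), "bp, frame offset", x$frame_offset, "\n")
  cat("populations:", paste(sprintf("%s=%d", names(table(x$population)),
                                    table(x$population)), collapse = ", "), "\n")
  invisible(x)
}

n_haplotype_copies <- function(aln) length(aln$sequences)
alignment_length <- function(aln) ncol(aln$mat)

#' Subset a phased alignment by individual
#'
#' @param aln a [phased_alignment()].
#' @param individuals character vector of individual ids to keep.
#' @return a new `phased_alignment`.
#' @export
subset_alignment <- function(aln, individuals) {
  keep <- aln$individual_id %in% individuals
  if (!any(keep)) stop("no matching individuals in alignment", call. = FALSE)
  phased_alignment(aln$sequences[keep], aln$individual_id[keep],
                   aln$haplotype_index[keep], aln$population[keep],
                   aln$frame_offset)
}

#' Read a phased haplotype FASTA file
#'
#' Headers must encode the individual id and haplotype index; by default the
#' convention is `<individual>_hap1` / `<individual>_hap2` and is
#' configurable through `header_regex`, whose first capture group is the
#' individual id and second the haplotype index.
#'
#' @param path FASTA file.
#' @param frame_offset 0-based position of the first complete codon.
#' @param header_regex regular expression with two capture groups.
#' @param population single population label, or a named character vector
#'   mapping individual id to population.
#' @return a [phased_alignment()].
#' @export
read_phased_fasta <- function(path, frame_offset = 0L,
                              header_regex = "^(.*)_hap([12])$",
                              population = "pop") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  m <- regmatches(headers, regexec(header_regex, headers))
  bad <- headers[vapply(m, length, integer(1)) != 3L]
  if (length(bad) > 0L) {
    stop("header(s) not matching pairing convention: ",
         paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  }
  ind <- vapply(m, `[[`, character(1), 2L)
  hap <- as.integer(vapply(m, `[[`, character(1), 3L))
  if (length(population) > 1L || !is.null(names(population))) {
    miss <- setdiff(unique(ind), names(population))
    if (length(miss) > 0L) {
      stop("no population label for individual(s): ",
           paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
    }
    pop <- unname(population[ind])
  } else {
    pop <- rep(population, length(ind))
  }
  phased_alignment(as.character(set), ind, hap, pop, frame_offset)
}

#' Write a phased alignment to FASTA
#'
#' Round-trips exactly with [read_phased_fasta()] under the default header
#' convention.
#'
#' @param aln a [phased_alignment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phased_fasta <- function(aln, path) {
  set <- Biostrings::BStringSet(aln$sequences)
  names(set) <- sprintf("%s_hap%d", aln$individual_id, aln$haplotype_index)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Construct a codon partition
#'
#' Partitions the codons of the amplicon reading frame into the putative
#' peptide-binding region (PBR) and the remainder (non-PBR). Codon indices
#' are 1-based within the reading frame.
#'
#' @param pbr_codons integer vector of 1-based PBR codon indices.
#' @param total_codons total number of codons in the frame.
#' @return an object of class `codon_partition`.
#' @export
codon_partition <- function(pbr_codons, total_codons) {
  total_codons <- as.integer(total_codons)
  pbr_codons <- sort(unique(as.integer(pbr_codons)))
  if (length(pbr_codons) > 0L &&
      (min(pbr_codons) < 1L || max(pbr_codons) > total_codons)) {
    stop("bounds error: PBR codon index outside 1..", total_codons,
         call. = FALSE)
  }
  structure(list(pbr_codons = pbr_codons, total_codons = total_codons),
            class = "codon_partition")
}

#' @export
print.codon_partition <- function(x, ...) {
  cat("codon_partition:", length(x$pbr_codons), "PBR /",
      x$total_codons - length(x$pbr_codons), "non-PBR /",
      x$total_codons, "codons\n")
  invisible(x)
}

partition_codons <- function(partition, site_class = c("all", "pbr", "nonpbr")) {
  site_class <- match.arg(site_class)
  all_codons <- seq_len(partition$total_codons)
  switch(site_class,
         all = all_codons,
         pbr = partition$pbr_codons,
         nonpbr = setdiff(all_codons, partition$pbr_codons))
}

#' Read a codon partition file
#'
#' Accepts either a JSON file (an array of codon indices, or an object with
#' a `pbr_codons` field) or a one-column text/TSV file of indices; a column
#' named `codon` is used when a header is present.
#'
#' @param path partition file (.json or text).
#' @param total_codons total codons in the reading frame.
#' @return a [codon_partition()].
#' @export
read_codon_partition <- function(path, total_codons) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
    idx <- if (is.list(parsed) && !is.null(parsed$pbr_codons)) {
      parsed$pbr_codons
    } else {
      parsed
    }
  } else {
    first <- readLines(path, n = 1L)
    has_header <- grepl("[A-Za-z]", first)
    tab <- utils::read.table(path, header = has_header, sep = "",
                             stringsAsFactors = FALSE)
    idx <- if (has_header && "codon" %in% names(tab)) tab$codon else tab[[1L]]
  }
  if (length(idx) > 0 && any(is.na(suppressWarnings(as.numeric(idx))))) {
    stop("format error: non-numeric codon index in ", path, call. = FALSE)
  }
  codon_partition(as.integer(idx), total_codons)
}

#' Construct a microsatellite genotype dataset
#'
#' @param individuals character vector of individual ids (unique).
#' @param loci character vector of locus names.
#' @param allele1,allele2 integer matrices (individuals x loci) of allele
#'   labels; `NA` in both marks a missing genotype. Pairs are stored
#'   unordered (sorted so `allele1 <= allele2`).
#' @param population character vector of population labels per individual.
#' @return an object of class `msat_dataset`.
#' @export
msat_dataset <- function(individuals, loci, allele1, allele2, population) {
  individuals <- as.character(individuals)
  if (anyDuplicated(individuals)) {
    stop("key error: duplicate individual_id", call. = FALSE)
  }
  loci <- as.character(loci)
  allele1 <- as.matrix(allele1); allele2 <- as.matrix(allele2)
  stopifnot(nrow(allele1) == length(individuals), ncol(allele1) == length(loci),
            identical(dim(allele1), dim(allele2)))
  if (length(population) == 1L) population <- rep(population, length(individuals))
  stopifnot(length(population) == length(individuals))
  half_missing <- xor(is.na(allele1), is.na(allele2))
  if (any(half_missing)) {
    stop("format error: genotype with exactly one missing allele", call. = FALSE)
  }
  ok <- !is.na(allele1)
  if (any(allele1[ok] < 1L) || any(allele2[ok] < 1L)) {
    stop("format error: allele labels must be positive integers", call. = FALSE)
  }
  lo <- pmin(allele1, allele2); hi <- pmax(allele1, allele2)
  dimnames(lo) <- dimnames(hi) <- list(individuals, loci)
  structure(list(individuals = individuals, loci = loci,
                 allele1 = lo, allele2 = hi,
                 population = as.character(population)),
            class = "msat_dataset")
}

#' @export
print.msat_dataset <- function(x, ...) {
  cat("msat_dataset:", length(x$individuals), "individuals x",
      length(x$loci), "loci;",
      sum(is.na(x$allele1)), "missing genotypes\n")
  invisible(x)
}

#' Subset a microsatellite dataset
#'
#' @param ds an [msat_dataset()].
#' @param individuals ids to keep (default all).
#' @param loci locus names to keep (default all).
#' @return a new `msat_dataset`.
#' @export
subset_msat <- function(ds, individuals = NULL, loci = NULL) {
  individuals <- individuals %||% ds$individuals
  loci <- loci %||% ds$loci
  ri <- match(individuals, ds$individuals)
  ci <- match(loci, ds$loci)
  if (anyNA(ri)) stop("unknown individual id(s)", call. = FALSE)
  if (anyNA(ci)) stop("unknown locus name(s)", call. = FALSE)
  msat_dataset(individuals, loci,
               ds$allele1[ri, ci, drop = FALSE],
               ds$allele2[ri, ci, drop = FALSE],
               ds$population[ri])
}

#' Read a microsatellite genotype CSV
#'
#' Expected layout: a header row with an `id` column, an optional
#' `population` column, and one column per locus holding the two allele
#' labels separated by `/` (e.g. `150/152`). Empty cells and `NA` are
#' missing genotypes.
#'
#' @param path CSV file.
#' @param population fallback population label when the file has no
#'   `population` column.
#' @return an [msat_dataset()].
#' @export
read_genotype_csv <- function(path, population = "pop") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (!"id" %in% names(tab)) stop("format error: no 'id' column", call. = FALSE)
  ids <- tab$id
  pop <- if ("population" %in% names(tab)) tab$population else rep(population, nrow(tab))
  locus_cols <- setdiff(names(tab), c("id", "population"))
  if (length(locus_cols) == 0L) stop("format error: no locus columns", call. = FALSE)
  parse_col <- function(v) {
    v <- trimws(v)
    miss <- is.na(v) | v == "" | toupper(v) == "NA"
    parts <- strsplit(v, "[/|:]")
    a1 <- rep(NA_integer_, length(v)); a2 <- a1
    for (i in which(!miss)) {
      p <- parts[[i]]
      if (length(p) != 2L) {
        stop("format error: genotype '", v[i], "' is not a two-allele pair",
             call. = FALSE)
      }
      suppressWarnings({x1 <- as.integer(p[1]); x2 <- as.integer(p[2])})
      if (is.na(x1) || is.na(x2)) {
        stop("format error: non-integer allele in '", v[i], "'", call. = FALSE)
      }
      a1[i] <- x1; a2[i] <- x2
    }
    list(a1 = a1, a2 = a2)
  }
  parsed <- lapply(locus_cols, function(lc) parse_col(tab[[lc]]))
  a1 <- do.call(cbind, lapply(parsed, `[[`, "a1"))
  a2 <- do.call(cbind, lapply(parsed, `[[`, "a2"))
  msat_dataset(ids, locus_cols, a1, a2, pop)
}

#' Write a microsatellite dataset to CSV
#'
#' Round-trips exactly with [read_genotype_csv()].
#'
#' @param ds an [msat_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(ds, path) {
  cells <- matrix("", nrow = length(ds$individuals), ncol = length(ds$loci))
  ok <- !is.na(ds$allele1)
  cells[ok] <- sprintf("%d/%d", ds$allele1[ok], ds$allele2[ok])
  out <- data.frame(id = ds$individuals, population = ds$population,
                    cells, check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("id", "population", ds$loci)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate an individual metadata CSV
#'
#' Required columns: `id`, `population`, `sex` (male/female/unknown) and
#' `age_class` (calf/juvenile/adult/unknown). Category vocabularies are
#' closed; unmapped strings are an error rather than silently coerced.
#'
#' @param path CSV file.
#' @return a data.frame of class `individual_metadata`.
#' @export
read_metadata_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  individual_metadata(tab)
}

#' Validate an individual metadata table
#'
#' @param tab data.frame with columns `id`, `population`, `sex`, `age_class`.
#' @return the validated table with class `individual_metadata`.
#' @export
individual_metadata <- function(tab) {
  need <- c("id", "population", "sex", "age_class")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("format error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$id)) stop("key error: duplicate individual id", call. = FALSE)
  bad_sex <- setdiff(unique(tab$sex), SEX_LEVELS)
  if (length(bad_sex) > 0L) {
    stop("vocabulary error: sex value(s) ", paste(bad_sex, collapse = ", "),
         " not in {", paste(SEX_LEVELS, collapse = ", "), "}", call. = FALSE)
  }
  bad_age <- setdiff(unique(tab$age_class), AGE_LEVELS)
  if (length(bad_age) > 0L) {
    stop("vocabulary error: age_class value(s) ", paste(bad_age, collapse = ", "),
         " not in {", paste(AGE_LEVELS, collapse = ", "), "}", call. = FALSE)
  }
  tab$id <- as.character(tab$id)
  class(tab) <- c("individual_metadata", "data.frame")
  tab
}
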
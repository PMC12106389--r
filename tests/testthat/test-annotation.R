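test_that("computed features follow positional arithmetic on the + strand", {
  drv <- derive_features(data.frame(start = c(100, 300), end = c(200, 400)),
                         "+", region_config())
  get <- function(ty) drv[drv$feature_type == ty, c("start", "end")]
  expect_equal(unlist(get("intron"), use.names = FALSE), c(201, 299))
  expect_equal(unlist(get("splice_donor"), use.names = FALSE), c(201, 202))
  expect_equal(unlist(get("splice_acceptor"), use.names = FALSE), c(298, 299))
  expect_equal(unlist(get("upstream"), use.names = FALSE), c(1, 99))  # clipped
  expect_equal(unlist(get("downstream"), use.names = FALSE), c(401, 5400))
  expect_equal(unlist(get("tss"), use.names = FALSE), c(100, 100))
})

test_that("computed features reflect strand on the - strand", {
  drv <- derive_features(data.frame(start = c(100, 300), end = c(200, 400)),
                         "-", region_config())
  get <- function(ty) drv[drv$feature_type == ty, c("start", "end")]
  expect_equal(unlist(get("intron"), use.names = FALSE), c(201, 299))
  expect_equal(unlist(get("splice_donor"), use.names = FALSE), c(298, 299))
  expect_equal(unlist(get("splice_acceptor"), use.names = FALSE), c(201, 202))
  expect_equal(unlist(get("upstream"), use.names = FALSE), c(401, 5400))
  expect_equal(unlist(get("tss"), use.names = FALSE), c(400, 400))
})

test_that("single-exon transcripts have no intronic features but keep flanks", {
  drv <- derive_features(data.frame(start = 1000, end = 2000), "+",
                         region_config())
  expect_false(any(drv$feature_type %in%
                     c("intron", "splice_donor", "splice_acceptor")))
  expect_setequal(drv$feature_type, c("upstream", "downstream", "tss"))
})

test_that("splice site windows are clamped inside short introns", {
  cfg <- region_config(splice_donor = 10, splice_acceptor = 10)
  drv <- derive_features(data.frame(start = c(100, 206), end = c(200, 300)),
                         "+", cfg)  # 5-bp intron
  intr <- drv[drv$feature_type == "intron", ]
  don <- drv[drv$feature_type == "splice_donor", ]
  acc <- drv[drv$feature_type == "splice_acceptor", ]
  expect_true(don$start >= intr$start && don$end <= intr$end)
  expect_true(acc$start >= intr$start && acc$end <= intr$end)
})

test_that("a 3-exon transcript yields 2 introns and one flank pair", {
  path <- withr::local_tempfile(fileext = ".gtf")
  write_tiny_gtf(path)
  ann <- load_gtf(path)
  tab <- table(ann$features$feature_type)
  expect_equal(unname(tab[["exon"]]), 3L)
  expect_equal(unname(tab[["intron"]]), 2L)
  expect_equal(unname(tab[["upstream"]]), 1L)
  expect_equal(unname(tab[["downstream"]]), 1L)
  expect_equal(nrow(ann$genes), 1L)
})

test_that("an empty GTF yields an empty annotation and empty queries", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines("#!genome-build none", path)
  ann <- load_gtf(path)
  expect_equal(nrow(ann$genes), 0L)
  expect_equal(nrow(suppressWarnings(query_point(ann, "chr1", 100))), 0L)
})

test_that("malformed GTF lines are rejected with their line number", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(gtf_line("chr1", "exon", 1L, 10L, "+", 'gene_id "G";'),
               "chr1\texon\tbroken"), path)
  expect_error(load_gtf(path), "line 2")
})

test_that("exon rows without a transcript_id become record-level errors", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    gtf_line("chr1", "transcript", 100L, 400L, "+",
             'gene_id "G1"; transcript_id "T1";'),
    gtf_line("chr1", "exon", 100L, 400L, "+",
             'gene_id "G1"; transcript_id "T1";'),
    gtf_line("chr1", "exon", 500L, 600L, "+", 'gene_id "G1";')
  ), path)
  ann <- load_gtf(path)
  expect_length(ann$record_errors, 1L)
  expect_match(ann$record_errors, "no transcript_id")
  expect_equal(sum(ann$features$feature_type == "exon"), 1L)
})

test_that("unknown feature keywords are skipped and counted", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    gtf_line("chr1", "transcript", 100L, 400L, "+",
             'gene_id "G1"; transcript_id "T1";'),
    gtf_line("chr1", "exon", 100L, 400L, "+",
             'gene_id "G1"; transcript_id "T1";'),
    gtf_line("chr1", "Selenocysteine", 150L, 152L, "+",
             'gene_id "G1"; transcript_id "T1";')
  ), path)
  ann <- load_gtf(path)
  expect_equal(ann$n_skipped, 1L)
})

test_that("duplicate feature rows are de-duplicated", {
  path <- withr::local_tempfile(fileext = ".gtf")
  a <- 'gene_id "G1"; transcript_id "T1";'
  writeLines(c(gtf_line("chr1", "transcript", 100L, 400L, "+", a),
               gtf_line("chr1", "exon", 100L, 400L, "+", a),
               gtf_line("chr1", "exon", 100L, 400L, "+", a)), path)
  ann <- load_gtf(path)
  expect_equal(sum(ann$features$feature_type == "exon"), 1L)
})

test_that("transcript spans are inferred when transcript rows are absent", {
  path <- withr::local_tempfile(fileext = ".gtf")
  a <- 'gene_id "G1"; transcript_id "T1";'
  writeLines(c(gtf_line("chr1", "exon", 100L, 200L, "+", a),
               gtf_line("chr1", "exon", 300L, 450L, "+", a)), path)
  ann <- load_gtf(path)
  expect_equal(ann$transcripts$start, 100L)
  expect_equal(ann$transcripts$end, 450L)
  expect_true("transcript" %in% ann$features$feature_type)
})

test_that("point queries report containing features in deterministic order", {
  path <- withr::local_tempfile(fileext = ".gtf")
  write_tiny_gtf(path)  # exons (100,200) (300,400) (600,700)
  ann <- load_gtf(path)
  h <- query_point(ann, "chr1", 150)
  expect_true(all(c("exon", "transcript") %in% h$feature_type))
  expect_false("tss" %in% h$feature_type)
  expect_equal(h, h[order(h$gene_id, h$transcript_id, h$feature_type), ],
               ignore_attr = TRUE)
  # intergenic desert: far beyond the downstream window
  expect_equal(nrow(query_point(ann, "chr1", 100000)), 0L)
  expect_warning(query_point(ann, "chrZ", 1), "not present")
  # tss exposed only on request
  expect_true("tss" %in% query_point(ann, "chr1", 100, include_tss = TRUE)$feature_type)
})

test_that("fixture annotation matches an independent re-parse of the GTF", {
  spec <- fixture_spec(seed = 1L)
  path <- withr::local_tempfile(fileext = ".gtf")
  make_gtf(spec, path)
  ann <- load_gtf(path)
  oracle <- reparse_gtf_counts(path)
  tab <- table(ann$features$feature_type)
  expect_equal(unname(tab[["exon"]]), oracle$n_exons)
  expect_equal(unname(tab[["intron"]]), oracle$n_introns)
  expect_equal(unname(tab[["transcript"]]), oracle$n_tx)
  expect_equal(unname(tab[["upstream"]]), oracle$n_upstream)
  expect_equal(unname(tab[["downstream"]]), oracle$n_downstream)
  expect_equal(unname(tab[["tss"]]), oracle$n_tx)
  # per-transcript intron counts: k exons force k - 1 introns
  introns <- ann$features[ann$features$feature_type == "intron", ]
  got <- table(introns$transcript_id)
  for (tid in names(oracle$exons_per_tx)) {
    k <- as.integer(oracle$exons_per_tx[[tid]])
    n_int <- if (tid %in% names(got)) as.integer(got[[tid]]) else 0L
    expect_equal(n_int, k - 1L)
  }
})

test_that("exons and introns exactly tile each transcript span", {
  ann <- fixture_annotation()
  f <- ann$features
  for (tid in ann$transcripts$transcript_id) {
    tx <- ann$transcripts[ann$transcripts$transcript_id == tid, ]
    pieces <- f[f$transcript_id == tid & f$feature_type %in% c("exon", "intron"),
                c("start", "end")]
    pieces <- pieces[order(pieces$start), ]
    expect_equal(pieces$start[1], tx$start)
    expect_equal(pieces$end[nrow(pieces)], tx$end)
    if (nrow(pieces) > 1)
      expect_equal(pieces$start[-1], pieces$end[-nrow(pieces)] + 1L)
  }
})

test_that("splice sites are subsets of their parent intron", {
  ann <- fixture_annotation()
  f <- ann$features
  for (tid in unique(f$transcript_id[f$feature_type == "intron"])) {
    intr <- f[f$transcript_id == tid & f$feature_type == "intron", ]
    ss <- f[f$transcript_id == tid &
              f$feature_type %in% c("splice_donor", "splice_acceptor"), ]
    for (i in seq_len(nrow(ss))) {
      inside <- any(intr$start <= ss$start[i] & intr$end >= ss$end[i])
      expect_true(inside)
    }
  }
})

test_that("derived features are symmetric under coordinate mirroring", {
  mirror_at <- 1e6L
  for (rep in 1:25) {
    set.seed(100 + rep)
    k <- sample(1:5, 1)
    starts <- sort(sample(20000:40000, k))
    lens <- sample(50:200, k, replace = TRUE)
    ex <- data.frame(start = starts + cumsum(c(0, rep(500, k - 1))),
                     end = starts + cumsum(c(0, rep(500, k - 1))) + lens)
    strand <- sample(c("+", "-"), 1)
    fwd <- derive_features(ex, strand, region_config())
    mirrored_ex <- data.frame(start = mirror_at - ex$end + 1L,
                              end = mirror_at - ex$start + 1L)
    flip <- if (strand == "+") "-" else "+"
    rev <- derive_features(mirrored_ex[order(mirrored_ex$start), ], flip,
                           region_config())
    key <- function(d) {
      d2 <- d[order(d$feature_type, d$start), ]
      paste(d2$feature_type, d2$start, d2$end)
    }
    refl <- data.frame(feature_type = rev$feature_type,
                       start = mirror_at - rev$end + 1L,
                       end = mirror_at - rev$start + 1L)
    expect_equal(key(fwd), key(refl))
  }
})

test_that("an annotation index round-trips through its portable file", {
  ann <- fixture_annotation()
  path <- withr::local_tempfile(fileext = ".rds")
  write_annotation(ann, path)
  ann2 <- read_annotation(path)
  expect_equal(ann2$features, ann$features)
  expect_equal(ann2$genes, ann$genes)
  expect_equal(ann2$config, ann$config)
})
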
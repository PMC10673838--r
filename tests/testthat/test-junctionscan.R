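test_that("junction templates concatenate retained parental arms", {
  tpl <- junction_template("AAAA", "CCCC", 4, 0)
  expect_equal(tpl$product_seq, "AAAACCCC")
  expect_equal(tpl$j, 4)
  tpl2 <- junction_template("AAAA", "CCCC", 2, 3)
  expect_equal(tpl2$product_seq, "AAC")
  expect_error(junction_template("AAAA", "CCCC", 5, 0), "cut_a")
  expect_error(junction_template("AAXA", "CCCC", 2, 0), "ACGTN")
})

test_that("guide cuts land 3 bp 5' of the PAM, strand-aware", {
  guide <- "ACTCCAGTCTTTCTAGAAGA"
  withr::with_seed(11, {
    left <- random_dna(30); right <- random_dna(30)
  })
  parent <- paste0(left, guide, "TGG", right)
  # independent string-slicing oracle: forward guide starts 0-based at 30,
  # blunt cut between protospacer positions 17 and 18 -> coordinate 47
  expect_equal(guide_cut_site(parent, guide), 30 + 17)

  # reverse-strand embedding must give the mirrored cut
  parent_rc <- oracle_revcomp(parent)
  expect_equal(guide_cut_site(parent_rc, guide),
               nchar(parent) - (30 + 17))

  # a product built from reverse-strand matches equals the product of the
  # forward computation on the reverse-complemented parent
  tpl_fwd <- build_predicted_junction(parent, parent, guide, guide)
  expect_equal(tpl_fwd$j, 47)

  expect_error(guide_cut_site(parent, "ACGTACGTACGTACGTACGT"), "not found")
  expect_error(guide_cut_site(paste0(parent, parent), guide), "2 times")
  no_pam <- paste0(left, guide, "TAT", right)
  expect_error(guide_cut_site(no_pam, guide), "PAM")
})

test_that("worked scar examples match the enumeration oracle", {
  tpl <- junction_template("TTTGGATCGATCCAAA", "A", 16, 1)
  expect_equal(tpl$product_seq, "TTTGGATCGATCCAAA")

  # 4-bp deletion with 4-bp junction ambiguity
  cl <- classify_junction("TTTGGATCCAAA", tpl, min_anchor = 0)
  expect_equal(cl$d, 4)
  expect_equal(cl$insertion, "")
  expect_equal(cl$mh_len, 4)
  expect_equal(cl$mh_seq, "GATC")
  o <- oracle_classify("TTTGGATCCAAA", tpl$product_seq)
  expect_equal(cl$d, o$d)
  expect_equal(nchar(cl$insertion), o$ilen)
  expect_equal(cl$mh_len, o$m)
  expect_equal(o$shift_range, 4)  # pure deletion: shift range equals m

  # identity read
  cl0 <- classify_junction(tpl$product_seq, tpl, min_anchor = 0)
  expect_equal(cl0$d, 0)
  expect_equal(cl0$insertion, "")
  expect_equal(cl0$mh_len, 0)

  # "TTTGG" + "TT" + "CCAAA": the trailing inserted T matches the product,
  # so the minimal decomposition absorbs it into the suffix anchor
  # (oracle-verified: d = 5, insertion "T", not the naive d = 6 / "TT")
  cl2 <- classify_junction("TTTGGTTCCAAA", tpl, min_anchor = 0)
  o2 <- oracle_classify("TTTGGTTCCAAA", tpl$product_seq)
  expect_equal(o2$d, 5)
  expect_equal(o2$ilen, 1)
  expect_equal(cl2$d, o2$d)
  expect_equal(nchar(cl2$insertion), o2$ilen)
  expect_equal(cl2$p, 5)
})

test_that("classification equals the brute-force oracle on random cases", {
  withr::with_seed(421, {
    for (i in 1:300) {
      L <- sample(10:80, 1)
      tpl <- random_product_template(L)
      read <- random_dna(sample(5:60, 1))
      o <- oracle_classify(read, tpl$product_seq)
      cl <- classify_junction(read, tpl, min_anchor = 0)
      expect_equal(cl$d, o$d)
      expect_equal(nchar(cl$insertion), o$ilen)
      expect_equal(cl$mh_len, o$m)
      # conservation invariants
      expect_equal(cl$p + cl$s + nchar(cl$insertion), nchar(read))
      expect_equal(cl$p + cl$s + cl$d, L)
    }
  })
})

test_that("read-based shift range equals product MH for deletion reads", {
  withr::with_seed(99, {
    for (i in 1:100) {
      L <- sample(30:80, 1)
      tpl <- random_product_template(L)
      d <- sample(1:10, 1)
      a <- sample(0:(L - d), 1)
      read <- paste0(substr(tpl$product_seq, 1, a),
                     substr(tpl$product_seq, a + d + 1, L))
      o <- oracle_classify(read, tpl$product_seq)
      cl <- classify_junction(read, tpl, min_anchor = 0)
      expect_equal(cl$mh_len, o$m)
      expect_equal(o$shift_range, o$m)
    }
  })
})

test_that("reverse-complement symmetry holds for d, insertion length, m", {
  withr::with_seed(77, {
    for (i in 1:100) {
      L <- sample(20:80, 1)
      tpl <- random_product_template(L)
      read <- random_dna(sample(10:60, 1))
      cl <- classify_junction(read, tpl, min_anchor = 0)
      tpl_rc <- junction_template(oracle_revcomp(tpl$product_seq), "A",
                                  L, 1L)
      cl_rc <- classify_junction(oracle_revcomp(read), tpl_rc,
                                 min_anchor = 0)
      expect_equal(cl_rc$d, cl$d)
      expect_equal(nchar(cl_rc$insertion), nchar(cl$insertion))
      expect_equal(cl_rc$mh_len, cl$mh_len)
    }
  })
})

test_that("N near the junction and short anchors trigger exclusion", {
  tpl <- junction_template("TTTGGATCGATCCAAA", "A", 16, 1)
  # N inside the unexplained core
  cl <- classify_junction("TTTGGNTCCAAA", tpl, min_anchor = 0)
  expect_true(cl$excluded)
  # clean read, but anchors below the default minimum of 10
  cl2 <- classify_junction("TTTGGATCCAAA", tpl)
  expect_true(cl2$excluded)
  # N anywhere breaks an exact anchor, so it is always junction-proximal
  # to the resulting call and excludes the read (unresolvable trace)
  tpl3 <- default_junction_template()
  read3 <- tpl3$product_seq
  substr(read3, 3, 3) <- "N"
  cl3 <- classify_junction(read3, tpl3, min_anchor = 0)
  expect_true(cl3$excluded)
})

test_that("deletion size summaries use the midpoint median and drop exclusions", {
  tpl <- default_junction_template()
  g <- gen_junction_reads(tpl, scar_sim_params(200, deletion_size_dist = 12,
                                               insertion_rate = 0, seed = 5))
  calls <- classify_junction(g$reads, tpl)
  ds <- deletion_sizes(calls)
  expect_equal(unname(ds$median), 12)
  expect_equal(length(ds$sizes), 200)

  fake <- data.frame(read_id = c("a", "b"), d = c(0, 37),
                     excluded = c(FALSE, FALSE))
  expect_equal(deletion_sizes(fake)$median, 18.5)
  fake1 <- data.frame(read_id = "a", d = 4, excluded = FALSE)
  expect_equal(deletion_sizes(fake1)$median, 4)
  all_ex <- data.frame(read_id = "a", d = 4, excluded = TRUE)
  expect_error(deletion_sizes(all_ex), "excluded")
})

test_that("position profiles equal independent per-coordinate recounts", {
  tpl <- default_junction_template()
  j <- tpl$j

  # single read deleting [j-2, j+2): indicator profile
  read <- paste0(substr(tpl$product_seq, 1, j - 2),
                 substr(tpl$product_seq, j + 3, nchar(tpl$product_seq)))
  calls <- classify_junction(read, tpl)
  prof <- position_profiles(calls, tpl, window = 10)
  covered <- prof$rel_coord >= -2 & prof$rel_coord < 2
  # the deletion may be reported slid within its MH class; coverage of the
  # deletion interval itself must still be exactly 4 coordinates wide
  expect_equal(sum(prof$del_freq), 4)
  expect_true(all(prof$del_freq %in% c(0, 1)))

  # identity read: all-zero deletion profile
  prof0 <- position_profiles(classify_junction(tpl$product_seq, tpl), tpl,
                             window = 10)
  expect_true(all(prof0$del_freq == 0))

  # 500 synthetic reads: profile equals direct summation over calls
  g <- gen_junction_reads(tpl, scar_sim_params(500, seed = 9))
  calls <- classify_junction(g$reads, tpl)
  prof <- position_profiles(calls, tpl, window = 30)
  keep <- calls[!calls$excluded, ]
  for (rc in c(-30, -7, 0, 3, 29)) {
    co <- j + rc
    expect_equal(prof$del_freq[prof$rel_coord == rc],
                 mean(keep$del_start <= co & co < keep$del_end))
    expect_equal(prof$mh_freq[prof$rel_coord == rc],
                 mean(keep$mh_len > 0 & keep$mh_start <= co & co < keep$mh_end))
  }
  expect_error(position_profiles(calls, tpl, window = 0), "window")
})

test_that("translocation frequency follows the positivity rule", {
  g <- rbind(c(TRUE, FALSE), c(FALSE, FALSE), c(TRUE, TRUE),
             c(FALSE, FALSE), c(FALSE, TRUE))
  expect_equal(translocation_frequency(g), 60)
  expect_equal(translocation_frequency(g, "all"), 20)
  expect_equal(translocation_frequency(g, "sum"), 40)
  expect_equal(translocation_frequency(matrix(FALSE, 5, 2)), 0)
  expect_equal(translocation_frequency(matrix(c(rep(TRUE, 2), rep(FALSE, 3)),
                                              ncol = 1)), 40)
  df <- data.frame(well = rep(1:5, 2), replicate = rep(1:2, each = 5),
                   detected = c(TRUE, FALSE, TRUE, FALSE, FALSE,
                                FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(translocation_frequency(df), 60)
  expect_error(translocation_frequency(data.frame(x = 1)), "columns")
})
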
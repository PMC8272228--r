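#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// ---- 8-connected component labeling ------------------------------------
// Iterative flood fill; labels are 1..n in discovery order, 0 = background.

// [[Rcpp::export]]
Rcpp::IntegerMatrix cpp_label8(const Rcpp::LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  Rcpp::IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++next;
      lab(r0, c0) = next;
      stack.push_back(std::make_pair(r0, c0));
      while (!stack.empty()) {
        const int r = stack.back().first, c = stack.back().second;
        stack.pop_back();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            const int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            if (mask(rr, cc) && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}

// ---- small CNN: conv3x3(pad 1) -> ReLU -> maxpool2 blocks + linear head --
// All kernels are 3x3 with zero padding 1 and stride 1; pooling is 2x2
// stride 2 with floor on odd dims. Layout: images column-major, channels as
// cube slices; flattening follows Armadillo's native cube order so R can
// reconstruct nothing -- the head weights live entirely on this side.

static mat im2col3(const cube& in) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  mat out(9 * C, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        const int k = c * 9 + (dr + 1) * 3 + (dc + 1);
        for (int col = 0; col < W; ++col) {
          const int sc = col + dc;
          if (sc < 0 || sc >= W) continue;
          for (int row = 0; row < H; ++row) {
            const int sr = row + dr;
            if (sr < 0 || sr >= H) continue;
            out(k, col * H + row) = in(sr, sc, c);
          }
        }
      }
    }
  }
  return out;
}

static cube col2im3(const mat& dcols, const int H, const int W, const int C) {
  cube out(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        const int k = c * 9 + (dr + 1) * 3 + (dc + 1);
        for (int col = 0; col < W; ++col) {
          const int sc = col + dc;
          if (sc < 0 || sc >= W) continue;
          for (int row = 0; row < H; ++row) {
            const int sr = row + dr;
            if (sr < 0 || sr >= H) continue;
            out(sr, sc, c) += dcols(k, col * H + row);
          }
        }
      }
    }
  }
  return out;
}

static cube maxpool2(const cube& in, ucube& sw) {
  const int Ho = in.n_rows / 2, Wo = in.n_cols / 2, C = in.n_slices;
  cube out(Ho, Wo, C);
  sw.set_size(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = in(2 * i, 2 * j, c);
        uword arg = 2 * j * in.n_rows + 2 * i;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const double v = in(2 * i + di, 2 * j + dj, c);
            if (v > best) {
              best = v;
              arg = (2 * j + dj) * in.n_rows + (2 * i + di);
            }
          }
        }
        out(i, j, c) = best;
        sw(i, j, c) = arg;
      }
    }
  }
  return out;
}

static cube unpool2(const cube& dout, const ucube& sw, const int H, const int W) {
  const int C = dout.n_slices;
  cube din(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* slice = din.slice_memptr(c);
    for (uword j = 0; j < dout.n_cols; ++j)
      for (uword i = 0; i < dout.n_rows; ++i)
        slice[sw(i, j, c)] += dout(i, j, c);
  }
  return din;
}

// One forward (and optionally backward) pass over a batch.
// X: H x W x N single-channel images; y: 0-based labels, -1 = unlabeled.
// convW[l]: (Cout_l x 9*Cin_l), convB[l]: Cout_l; Wd: K x nfeat, bd: K.
// Returns mean loss/accuracy over labeled items, N x K probabilities and,
// if backward, gradients averaged over the batch.

// [[Rcpp::export]]
Rcpp::List cpp_cnn_batch(const arma::cube& X, const arma::ivec& y,
                         const Rcpp::List& convW, const Rcpp::List& convB,
                         const arma::mat& Wd, const arma::vec& bd,
                         const bool backward) {
  const int N = X.n_slices, L = convW.size(), K = Wd.n_rows;
  std::vector<mat> W(L);
  std::vector<vec> b(L);
  for (int l = 0; l < L; ++l) {
    W[l] = Rcpp::as<mat>(convW[l]);
    b[l] = Rcpp::as<vec>(convB[l]);
  }
  std::vector<mat> gW(L);
  std::vector<vec> gb(L);
  for (int l = 0; l < L; ++l) {
    gW[l] = zeros<mat>(W[l].n_rows, W[l].n_cols);
    gb[l] = zeros<vec>(b[l].n_elem);
  }
  mat gWd = zeros<mat>(Wd.n_rows, Wd.n_cols);
  vec gbd = zeros<vec>(bd.n_elem);
  mat probs(N, K);
  double loss = 0.0;
  int n_lab = 0, n_correct = 0;

  std::vector<mat> cols(L);
  std::vector<umat> relu_pos(L);
  std::vector<ucube> sw(L);
  std::vector<int> inH(L), inW(L), inC(L);

  for (int n = 0; n < N; ++n) {
    cube cur(X.n_rows, X.n_cols, 1);
    cur.slice(0) = X.slice(n);
    for (int l = 0; l < L; ++l) {
      inH[l] = cur.n_rows; inW[l] = cur.n_cols; inC[l] = cur.n_slices;
      cols[l] = im2col3(cur);
      mat pre = W[l] * cols[l];
      pre.each_col() += b[l];
      relu_pos[l] = conv_to<umat>::from(pre > 0);
      pre %= conv_to<mat>::from(relu_pos[l]);
      // pre is Cout x (H*W): reshape to cube H x W x Cout
      cube act(inH[l], inW[l], W[l].n_rows);
      for (uword c = 0; c < act.n_slices; ++c)
        act.slice(c) = reshape(pre.row(c), inH[l], inW[l]);
      cur = maxpool2(act, sw[l]);
    }
    vec f = vectorise(cur);
    vec z = Wd * f + bd;
    z -= z.max();
    vec p = exp(z);
    p /= accu(p);
    probs.row(n) = p.t();

    const int yi = y(n);
    vec dz;
    if (yi >= 0) {
      loss += -std::log(std::max(p(yi), 1e-12));
      ++n_lab;
      if ((int)p.index_max() == yi) ++n_correct;
    }
    if (!backward || yi < 0) continue;

    dz = p;
    dz(yi) -= 1.0;
    gWd += dz * f.t();
    gbd += dz;
    vec df = Wd.t() * dz;
    cube dcur(cur.n_rows, cur.n_cols, cur.n_slices);
    std::copy(df.begin(), df.end(), dcur.begin());
    for (int l = L - 1; l >= 0; --l) {
      cube dact = unpool2(dcur, sw[l], inH[l], inW[l]);
      // back to Cout x (H*W)
      mat dpre(W[l].n_rows, inH[l] * inW[l]);
      for (uword c = 0; c < dact.n_slices; ++c)
        dpre.row(c) = vectorise(dact.slice(c)).t();
      dpre %= conv_to<mat>::from(relu_pos[l]);
      gW[l] += dpre * cols[l].t();
      gb[l] += sum(dpre, 1);
      if (l > 0) {
        mat dcols = W[l].t() * dpre;
        dcur = col2im3(dcols, inH[l], inW[l], inC[l]);
      }
    }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("loss") = n_lab ? loss / n_lab : NA_REAL,
    Rcpp::Named("acc") = n_lab ? (double)n_correct / n_lab : NA_REAL,
    Rcpp::Named("probs") = probs);
  if (backward && n_lab > 0) {
    Rcpp::List oW(L), ob(L);
    for (int l = 0; l < L; ++l) {
      oW[l] = gW[l] / n_lab;
      ob[l] = gb[l] / n_lab;
    }
    out["gW"] = oW;
    out["gb"] = ob;
    out["gWd"] = gWd / n_lab;
    out["gbd"] = gbd / n_lab;
  }
  return out;
}
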
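// Compact serial CNN: conv(3x3, same, stride 1) -> batch-norm -> ReLU ->
// max-pool blocks, a fully connected head and softmax.  Convolutions are
// evaluated as im2col + GEMM; training-mode batch normalization is computed
// over the mini-batch, inference uses running moments supplied from R.
// All randomness (init, shuffling) lives on the R side, so a forward or
// forward+backward pass here is deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static const int N_BLOCKS = 5;
// 2x2 max-pool strides after blocks 1..4 (none after block 5); strides 1,1,2,2
// reproduce the spatial trajectory 24->23->22->11->5 of the architecture.
static const int POOL_STRIDE[4] = {1, 1, 2, 2};
static const double BN_EPS = 1e-5;

// ---- im2col / col2im for 3x3 same-padding kernels ------------------------

static mat im2col3(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(H * W, 9 * C, fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        mat s(H, W, fill::zeros);
        const int r0 = std::max(0, -dy), r1 = std::min(H, H - dy);
        const int c0 = std::max(0, -dx), c1 = std::min(W, W - dx);
        if (r1 > r0 && c1 > c0) {
          s.submat(r0, c0, r1 - 1, c1 - 1) =
            x.slice(c).submat(r0 + dy, c0 + dx, r1 - 1 + dy, c1 - 1 + dx);
        }
        out.col(col++) = vectorise(s);
      }
    }
  }
  return out;
}

static cube col2im3(const mat& dcols, int H, int W, int C) {
  cube dx_(H, W, C, fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    for (int dxo = -1; dxo <= 1; ++dxo) {
      for (int dy = -1; dy <= 1; ++dy) {
        mat m = reshape(dcols.col(col++), H, W);
        const int r0 = std::max(0, -dy), r1 = std::min(H, H - dy);
        const int c0 = std::max(0, -dxo), c1 = std::min(W, W - dxo);
        if (r1 > r0 && c1 > c0) {
          dx_.slice(c).submat(r0 + dy, c0 + dxo, r1 - 1 + dy, c1 - 1 + dxo) +=
            m.submat(r0, c0, r1 - 1, c1 - 1);
        }
      }
    }
  }
  return dx_;
}

static cube mat2cube(const mat& z, int H, int W) {
  cube out(H, W, z.n_cols);
  for (uword c = 0; c < z.n_cols; ++c) out.slice(c) = reshape(z.col(c), H, W);
  return out;
}

static mat cube2mat(const cube& z) {
  mat out(z.n_rows * z.n_cols, z.n_slices);
  for (uword c = 0; c < z.n_slices; ++c) out.col(c) = vectorise(z.slice(c));
  return out;
}

// ---- 2x2 max pooling ------------------------------------------------------

static cube pool_fwd(const cube& x, int stride, ucube& arg) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H - 2) / stride + 1, Wo = (W - 2) / stride + 1;
  cube out(Ho, Wo, C);
  arg.set_size(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int r = i * stride, cc = j * stride;
        double best = x(r, cc, c);
        uword bi = r + cc * H;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const double v = x(r + di, cc + dj, c);
            if (v > best) { best = v; bi = (r + di) + (cc + dj) * H; }
          }
        }
        out(i, j, c) = best;
        arg(i, j, c) = bi;
      }
    }
  }
  return out;
}

static cube pool_bwd(const cube& dout, const ucube& arg, int H, int W) {
  cube dx_(H, W, dout.n_slices, fill::zeros);
  for (uword c = 0; c < dout.n_slices; ++c) {
    for (uword j = 0; j < dout.n_cols; ++j) {
      for (uword i = 0; i < dout.n_rows; ++i) {
        dx_.slice(c)(arg(i, j, c)) += dout(i, j, c);
      }
    }
  }
  return dx_;
}

// ---- the network pass -----------------------------------------------------

struct BlockCache {
  std::vector<mat> cols;     // im2col of the block input, per sample
  std::vector<cube> xhat;    // normalized pre-activation
  std::vector<cube> relu_in; // BN output (ReLU input)
  std::vector<ucube> poolarg;
  int in_H, in_W, in_C;
  vec mu, invstd;
};

// [[Rcpp::export]]
List cnn_pass(List params, List xlist, Rcpp::IntegerVector y, bool training,
              List run_stats) {
  const int B = xlist.size();
  std::vector<mat> Wc(N_BLOCKS);
  std::vector<vec> bc(N_BLOCKS), gamma(N_BLOCKS), beta(N_BLOCKS);
  for (int l = 0; l < N_BLOCKS; ++l) {
    Wc[l] = Rcpp::as<mat>(params[std::string("W") + std::to_string(l + 1)]);
    bc[l] = Rcpp::as<vec>(params[std::string("b") + std::to_string(l + 1)]);
    gamma[l] = Rcpp::as<vec>(params[std::string("g") + std::to_string(l + 1)]);
    beta[l] = Rcpp::as<vec>(params[std::string("be") + std::to_string(l + 1)]);
  }
  mat Wfc = Rcpp::as<mat>(params["Wfc"]);
  vec bfc = Rcpp::as<vec>(params["bfc"]);

  std::vector<cube> act(B);
  for (int s = 0; s < B; ++s) {
    mat m = Rcpp::as<mat>(xlist[s]);
    act[s] = cube(m.n_rows, m.n_cols, 1);
    act[s].slice(0) = m;
  }

  const bool want_grad = y.size() > 0;
  std::vector<BlockCache> cache(N_BLOCKS);
  List batch_means(N_BLOCKS), batch_vars(N_BLOCKS);

  for (int l = 0; l < N_BLOCKS; ++l) {
    BlockCache& cb = cache[l];
    const int H = act[0].n_rows, W = act[0].n_cols, Cin = act[0].n_slices;
    const int Cout = Wc[l].n_cols;
    cb.in_H = H; cb.in_W = W; cb.in_C = Cin;
    std::vector<cube> z(B);
    for (int s = 0; s < B; ++s) {
      mat cols = im2col3(act[s]);
      mat zm = cols * Wc[l];
      zm.each_row() += bc[l].t();
      z[s] = mat2cube(zm, H, W);
      if (want_grad) cb.cols.push_back(std::move(cols));
    }
    // batch normalization per output channel
    vec mu(Cout), var_(Cout);
    if (training) {
      const double mtot = (double)B * H * W;
      for (int c = 0; c < Cout; ++c) {
        double sum = 0, sq = 0;
        for (int s = 0; s < B; ++s) {
          sum += accu(z[s].slice(c));
          sq += accu(square(z[s].slice(c)));
        }
        mu(c) = sum / mtot;
        var_(c) = sq / mtot - mu(c) * mu(c);
        if (var_(c) < 0) var_(c) = 0;
      }
    } else {
      mu = Rcpp::as<vec>(run_stats[std::string("rm") + std::to_string(l + 1)]);
      var_ = Rcpp::as<vec>(run_stats[std::string("rv") + std::to_string(l + 1)]);
    }
    vec invstd = 1.0 / sqrt(var_ + BN_EPS);
    batch_means[l] = mu;
    batch_vars[l] = var_;
    cb.mu = mu; cb.invstd = invstd;

    for (int s = 0; s < B; ++s) {
      cube xh(H, W, Cout), out(H, W, Cout);
      for (int c = 0; c < Cout; ++c) {
        xh.slice(c) = (z[s].slice(c) - mu(c)) * invstd(c);
        out.slice(c) = gamma[l](c) * xh.slice(c) + beta[l](c);
      }
      if (want_grad) { cb.xhat.push_back(xh); cb.relu_in.push_back(out); }
      // ReLU
      out.transform([](double v) { return v > 0 ? v : 0.0; });
      if (l < 4) {
        ucube arg;
        cube pooled = pool_fwd(out, POOL_STRIDE[l], arg);
        if (want_grad) cb.poolarg.push_back(std::move(arg));
        act[s] = std::move(pooled);
      } else {
        act[s] = std::move(out);
      }
    }
  }

  // fully connected + softmax
  const int fH = act[0].n_rows, fW = act[0].n_cols, fC = act[0].n_slices;
  mat probs(B, Wfc.n_rows);
  mat dlogits(B, Wfc.n_rows, fill::zeros);
  std::vector<vec> flats(B);
  double loss = 0;
  for (int s = 0; s < B; ++s) {
    flats[s] = vectorise(act[s]);
    vec logits = Wfc * flats[s] + bfc;
    vec e = exp(logits - logits.max());
    vec p = e / accu(e);
    probs.row(s) = p.t();
    if (want_grad) {
      const int cls = y[s];  // 0-based class index
      loss += -std::log(std::max(p(cls), 1e-12));
      vec d = p;
      d(cls) -= 1.0;
      dlogits.row(s) = d.t() / (double)B;
    }
  }

  if (!want_grad) {
    return List::create(Named("probs") = probs);
  }
  loss /= (double)B;

  // ---- backward ----
  mat dWfc(size(Wfc), fill::zeros);
  vec dbfc(Wfc.n_rows, fill::zeros);
  std::vector<cube> dact(B);
  for (int s = 0; s < B; ++s) {
    dWfc += dlogits.row(s).t() * flats[s].t();
    dbfc += dlogits.row(s).t();
    vec dflat = Wfc.t() * dlogits.row(s).t();
    dact[s] = cube(dflat.memptr(), fH, fW, fC);
  }

  List grads;
  grads["Wfc"] = dWfc;
  grads["bfc"] = dbfc;

  for (int l = N_BLOCKS - 1; l >= 0; --l) {
    BlockCache& cb = cache[l];
    const int H = cb.in_H, W = cb.in_W;
    const int Cout = Wc[l].n_cols;
    const double mtot = (double)B * H * W;

    // through pooling (blocks 1..4) and ReLU
    std::vector<cube> dbn(B);
    for (int s = 0; s < B; ++s) {
      cube d = (l < 4) ? pool_bwd(dact[s], cb.poolarg[s], H, W)
                       : dact[s];
      const cube& rin = cb.relu_in[s];
      for (int c = 0; c < Cout; ++c) {
        d.slice(c) %= conv_to<mat>::from(rin.slice(c) > 0);
      }
      dbn[s] = std::move(d);
    }

    // batch-norm backward
    vec dgamma(Cout, fill::zeros), dbeta(Cout, fill::zeros);
    std::vector<cube> dz(B, cube(H, W, Cout));
    for (int c = 0; c < Cout; ++c) {
      double sum_dy = 0, sum_dy_xhat = 0;
      for (int s = 0; s < B; ++s) {
        sum_dy += accu(dbn[s].slice(c));
        sum_dy_xhat += accu(dbn[s].slice(c) % cb.xhat[s].slice(c));
      }
      dgamma(c) = sum_dy_xhat;
      dbeta(c) = sum_dy;
      const double k = gamma[l](c) * cb.invstd(c) / mtot;
      for (int s = 0; s < B; ++s) {
        dz[s].slice(c) = k * (mtot * dbn[s].slice(c) - sum_dy -
                              cb.xhat[s].slice(c) * sum_dy_xhat);
      }
    }

    // convolution backward
    mat dW(size(Wc[l]), fill::zeros);
    vec db(Cout, fill::zeros);
    for (int s = 0; s < B; ++s) {
      mat dzm = cube2mat(dz[s]);
      dW += cb.cols[s].t() * dzm;
      db += sum(dzm, 0).t();
      mat dcols = dzm * Wc[l].t();
      dact[s] = col2im3(dcols, H, W, cb.in_C);
    }
    const std::string i = std::to_string(l + 1);
    grads["W" + i] = dW;
    grads["b" + i] = db;
    grads["g" + i] = dgamma;
    grads["be" + i] = dbeta;
  }

  return List::create(
    Named("probs") = probs,
    Named("loss") = loss,
    Named("grads") = grads,
    Named("batch_means") = batch_means,
    Named("batch_vars") = batch_vars
  );
}
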
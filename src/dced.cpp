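// Deep convolutional encoder-decoder: forward pass, backprop and the
// boundary matching kernel for the BF score.
//
// Feature maps are arma::cube (H x W x C).  A 3x3 "same" convolution stores
// its weights as a cube W(3, 3, Cin * Cout) with slice index i + Cin * o;
// learning makes the kernel-flip convention immaterial.  Layers arrive from
// R as a list of lists: type "conv" (fields W, b, relu), "pool" (2x2 max,
// stride 2) or "upsample" (2x nearest).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

arma::cube conv3_forward(const arma::cube& X, const arma::cube& W,
                         const arma::vec& b) {
  const int H = X.n_rows, Wd = X.n_cols;
  const int Cin = X.n_slices, Cout = b.n_elem;
  arma::cube Y(H, Wd, Cout);
  for (int o = 0; o < Cout; ++o) Y.slice(o).fill(b(o));
  for (int o = 0; o < Cout; ++o) {
    for (int i = 0; i < Cin; ++i) {
      const arma::mat& Xi = X.slice(i);
      arma::mat& Yo = Y.slice(o);
      const arma::mat& K = W.slice(i + Cin * o);
      for (int dr = -1; dr <= 1; ++dr) {
        for (int dc = -1; dc <= 1; ++dc) {
          const double w = K(dr + 1, dc + 1);
          if (w == 0.0) continue;
          const int r0y = std::max(0, -dr), r1y = H - 1 - std::max(0, dr);
          const int c0y = std::max(0, -dc), c1y = Wd - 1 - std::max(0, dc);
          if (r0y > r1y || c0y > c1y) continue;
          Yo.submat(r0y, c0y, r1y, c1y) +=
              w * Xi.submat(r0y + dr, c0y + dc, r1y + dr, c1y + dc);
        }
      }
    }
  }
  return Y;
}

// Backward through a 3x3 same conv: fills dX, dW, db given upstream dY.
void conv3_backward(const arma::cube& X, const arma::cube& W,
                    const arma::cube& dY, arma::cube& dX, arma::cube& dW,
                    arma::vec& db) {
  const int H = X.n_rows, Wd = X.n_cols;
  const int Cin = X.n_slices, Cout = dY.n_slices;
  dX.zeros(H, Wd, Cin);
  dW.zeros(3, 3, Cin * Cout);
  db.zeros(Cout);
  for (int o = 0; o < Cout; ++o) db(o) = arma::accu(dY.slice(o));
  for (int o = 0; o < Cout; ++o) {
    const arma::mat& dYo = dY.slice(o);
    for (int i = 0; i < Cin; ++i) {
      const arma::mat& Xi = X.slice(i);
      arma::mat& dXi = dX.slice(i);
      const arma::mat& K = W.slice(i + Cin * o);
      arma::mat& dK = dW.slice(i + Cin * o);
      for (int dr = -1; dr <= 1; ++dr) {
        for (int dc = -1; dc <= 1; ++dc) {
          const int r0y = std::max(0, -dr), r1y = H - 1 - std::max(0, dr);
          const int c0y = std::max(0, -dc), c1y = Wd - 1 - std::max(0, dc);
          if (r0y > r1y || c0y > c1y) continue;
          const arma::mat dYsub = dYo.submat(r0y, c0y, r1y, c1y);
          dK(dr + 1, dc + 1) += arma::accu(
              dYsub % Xi.submat(r0y + dr, c0y + dc, r1y + dr, c1y + dc));
          dXi.submat(r0y + dr, c0y + dc, r1y + dr, c1y + dc) +=
              K(dr + 1, dc + 1) * dYsub;
        }
      }
    }
  }
}

arma::cube pool_forward(const arma::cube& X, arma::ucube& argmax) {
  const int Ho = X.n_rows / 2, Wo = X.n_cols / 2, C = X.n_slices;
  arma::cube Y(Ho, Wo, C);
  argmax.set_size(Ho, Wo, C);
  for (int k = 0; k < C; ++k) {
    const arma::mat& Xi = X.slice(k);
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        double best = Xi(2 * r, 2 * c);
        unsigned int bi = 0;
        for (unsigned int j = 1; j < 4; ++j) {
          const double v = Xi(2 * r + (j & 1u), 2 * c + (j >> 1u));
          if (v > best) { best = v; bi = j; }
        }
        Y(r, c, k) = best;
        argmax(r, c, k) = bi;
      }
    }
  }
  return Y;
}

arma::cube pool_backward(const arma::cube& dY, const arma::ucube& argmax) {
  const int Ho = dY.n_rows, Wo = dY.n_cols, C = dY.n_slices;
  arma::cube dX(2 * Ho, 2 * Wo, C, arma::fill::zeros);
  for (int k = 0; k < C; ++k) {
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        const unsigned int j = argmax(r, c, k);
        dX(2 * r + (j & 1u), 2 * c + (j >> 1u), k) = dY(r, c, k);
      }
    }
  }
  return dX;
}

// Max-unpooling: place each value at the position recorded by the
// matching encoder pool, zeros elsewhere.
arma::cube unpool_forward(const arma::cube& X, const arma::ucube& idx) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  arma::cube Y(2 * H, 2 * W, C, arma::fill::zeros);
  for (int k = 0; k < C; ++k) {
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        const unsigned int j = idx(r, c, k);
        Y(2 * r + (j & 1u), 2 * c + (j >> 1u), k) = X(r, c, k);
      }
    }
  }
  return Y;
}

arma::cube unpool_backward(const arma::cube& dY, const arma::ucube& idx) {
  const int Ho = dY.n_rows / 2, Wo = dY.n_cols / 2, C = dY.n_slices;
  arma::cube dX(Ho, Wo, C);
  for (int k = 0; k < C; ++k) {
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        const unsigned int j = idx(r, c, k);
        dX(r, c, k) = dY(2 * r + (j & 1u), 2 * c + (j >> 1u), k);
      }
    }
  }
  return dX;
}

arma::cube upsample_forward(const arma::cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  arma::cube Y(2 * H, 2 * W, C);
  for (int k = 0; k < C; ++k) {
    for (int c = 0; c < 2 * W; ++c) {
      for (int r = 0; r < 2 * H; ++r) {
        Y(r, c, k) = X(r / 2, c / 2, k);
      }
    }
  }
  return Y;
}

arma::cube upsample_backward(const arma::cube& dY) {
  const int Ho = dY.n_rows / 2, Wo = dY.n_cols / 2, C = dY.n_slices;
  arma::cube dX(Ho, Wo, C, arma::fill::zeros);
  for (int k = 0; k < C; ++k) {
    for (int c = 0; c < 2 * Wo; ++c) {
      for (int r = 0; r < 2 * Ho; ++r) {
        dX(r / 2, c / 2, k) += dY(r, c, k);
      }
    }
  }
  return dX;
}

// Per-pixel softmax along slices.
arma::cube softmax_cube(const arma::cube& Z) {
  const int H = Z.n_rows, W = Z.n_cols, K = Z.n_slices;
  arma::cube P(H, W, K);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double m = Z(r, c, 0);
      for (int k = 1; k < K; ++k) m = std::max(m, Z(r, c, k));
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        const double e = std::exp(Z(r, c, k) - m);
        P(r, c, k) = e;
        s += e;
      }
      for (int k = 0; k < K; ++k) P(r, c, k) /= s;
    }
  }
  return P;
}

}  // namespace

// Run the network on one image.  `target` (H x W, values 0..K-1) switches on
// loss/accuracy computation; `want_grads` additionally runs backprop.
// `class_weights` (length K) weights the cross-entropy per true class.
// [[Rcpp::export]]
List cpp_dced_run(const arma::cube& image, List layers,
                  Nullable<IntegerMatrix> target = R_NilValue,
                  Nullable<NumericVector> class_weights = R_NilValue,
                  bool want_grads = false) {
  const int L = layers.size();
  std::vector<arma::cube> acts(L + 1);
  std::vector<arma::ucube> pool_idx(L);
  std::vector<int> unpool_src(L, -1);  // upsample layer -> pool layer used
  std::vector<int> pool_stack;
  acts[0] = image;

  for (int l = 0; l < L; ++l) {
    List lay = layers[l];
    const std::string type = as<std::string>(lay["type"]);
    if (type == "conv") {
      arma::cube W = as<arma::cube>(lay["W"]);
      arma::vec b = as<arma::vec>(lay["b"]);
      arma::cube Y = conv3_forward(acts[l], W, b);
      if (as<bool>(lay["relu"])) Y.transform([](double v) { return v > 0 ? v : 0.0; });
      acts[l + 1] = std::move(Y);
    } else if (type == "pool") {
      if (acts[l].n_rows % 2 || acts[l].n_cols % 2)
        stop("pool layer requires even spatial dims, got %dx%d",
             (int)acts[l].n_rows, (int)acts[l].n_cols);
      acts[l + 1] = pool_forward(acts[l], pool_idx[l]);
      pool_stack.push_back(l);
    } else if (type == "upsample") {
      std::string method = lay.containsElementNamed("method")
                               ? as<std::string>(lay["method"])
                               : "unpool";
      if (method == "unpool" && !pool_stack.empty()) {
        const int src = pool_stack.back();
        const arma::ucube& idx = pool_idx[src];
        if (idx.n_rows == acts[l].n_rows && idx.n_cols == acts[l].n_cols &&
            idx.n_slices == acts[l].n_slices) {
          pool_stack.pop_back();
          unpool_src[l] = src;
          acts[l + 1] = unpool_forward(acts[l], idx);
        } else {
          acts[l + 1] = upsample_forward(acts[l]);  // asymmetric spec
        }
      } else {
        acts[l + 1] = upsample_forward(acts[l]);
      }
    } else {
      stop("unknown layer type '%s'", type.c_str());
    }
  }

  arma::cube P = softmax_cube(acts[L]);
  List out = List::create(Named("scores") = P);

  if (target.isNull()) return out;

  IntegerMatrix tg(target);
  const int H = P.n_rows, W = P.n_cols, K = P.n_slices;
  if (tg.nrow() != H || tg.ncol() != W)
    stop("target shape %dx%d does not match output %dx%d", tg.nrow(),
         tg.ncol(), H, W);
  arma::vec wts(K, arma::fill::ones);
  if (class_weights.isNotNull()) wts = as<arma::vec>(NumericVector(class_weights));

  double loss = 0.0, wtot = 0.0;
  long correct = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const int y = tg(r, c);
      if (y < 0 || y >= K) stop("target label %d outside [0,%d]", y, K - 1);
      const double w = wts(y);
      loss -= w * std::log(std::max(P(r, c, y), 1e-12));
      wtot += w;
      int am = 0;
      for (int k = 1; k < K; ++k) if (P(r, c, k) > P(r, c, am)) am = k;
      if (am == y) ++correct;
    }
  }
  loss /= std::max(wtot, 1e-12);
  out["loss"] = loss;
  out["accuracy"] = (double)correct / (H * W);

  if (!want_grads) return out;

  // d(loss)/d(logits): w_y * (p - onehot) / wtot
  arma::cube dA = P;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const int y = tg(r, c);
      const double w = wts(y) / wtot;
      for (int k = 0; k < K; ++k) dA(r, c, k) *= w;
      dA(r, c, y) -= wts(y) / wtot;
    }
  }

  List grads(L);
  for (int l = L - 1; l >= 0; --l) {
    List lay = layers[l];
    const std::string type = as<std::string>(lay["type"]);
    if (type == "conv") {
      if (as<bool>(lay["relu"])) {
        const arma::cube& A = acts[l + 1];
        for (arma::uword i = 0; i < dA.n_elem; ++i)
          if (A(i) <= 0.0) dA(i) = 0.0;
      }
      arma::cube W = as<arma::cube>(lay["W"]);
      arma::cube dX, dW;
      arma::vec db;
      conv3_backward(acts[l], W, dA, dX, dW, db);
      grads[l] = List::create(Named("W") = dW, Named("b") = db);
      dA = std::move(dX);
    } else if (type == "pool") {
      grads[l] = R_NilValue;
      dA = pool_backward(dA, pool_idx[l]);
    } else {  // upsample
      grads[l] = R_NilValue;
      dA = (unpool_src[l] >= 0) ? unpool_backward(dA, pool_idx[unpool_src[l]])
                                : upsample_backward(dA);
    }
  }
  out["grads"] = grads;
  return out;
}

// For each row of A (point coordinates), is there a row of B within
// Euclidean distance `tol`?  Returns the count of matched A points.
// [[Rcpp::export]]
int cpp_count_matched(const arma::mat& A, const arma::mat& B, double tol) {
  const double t2 = tol * tol;
  int matched = 0;
  for (arma::uword i = 0; i < A.n_rows; ++i) {
    const double ar = A(i, 0), ac = A(i, 1);
    for (arma::uword j = 0; j < B.n_rows; ++j) {
      const double dr = ar - B(j, 0), dc = ac - B(j, 1);
      if (dr * dr + dc * dc <= t2) { ++matched; break; }
    }
  }
  return matched;
}
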
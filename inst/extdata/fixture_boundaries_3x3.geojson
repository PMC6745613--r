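{"type":"FeatureCollection","features":[{"type":"Feature","properties":{"id":"A001"},"geometry":{"type":"Polygon","coordinates":[[[0,0],[0.33333333333,0],[0.33333333333,0.33333333333],[0,0.33333333333],[0,0]]]}},{"type":"Feature","properties":{"id":"A002"},"geometry":{"type":"Polygon","coordinates":[[[0.33333333333,0],[0.66666666667,0],[0.66666666667,0.33333333333],[0.33333333333,0.33333333333],[0.33333333333,0]]]}},{"type":"Feature","properties":{"id":"A003"},"geometry":{"type":"Polygon","coordinates":[[[0.66666666667,0],[1,0],[1,0.33333333333],[0.66666666667,0.33333333333],[0.66666666667,0]]]}},{"type":"Feature","properties":{"id":"A004"},"geometry":{"type":"Polygon","coordinates":[[[0,0.33333333333],[0.33333333333,0.33333333333],[0.33333333333,0.66666666667],[0,0.66666666667],[0,0.33333333333]]]}},{"type":"Feature","properties":{"id":"A005"},"geometry":{"type":"Polygon","coordinates":[[[0.33333333333,0.33333333333],[0.66666666667,0.33333333333],[0.66666666667,0.66666666667],[0.33333333333,0.66666666667],[0.33333333333,0.33333333333]]]}},{"type":"Feature","properties":{"id":"A006"},"geometry":{"type":"Polygon","coordinates":[[[0.66666666667,0.33333333333],[1,0.33333333333],[1,0.66666666667],[0.66666666667,0.66666666667],[0.66666666667,0.33333333333]]]}},{"type":"Feature","properties":{"id":"A007"},"geometry":{"type":"Polygon","coordinates":[[[0,0.66666666667],[0.33333333333,0.66666666667],[0.33333333333,1],[0,1],[0,0.66666666667]]]}},{"type":"Feature","properties":{"id":"A008"},"geometry":{"type":"Polygon","coordinates":[[[0.33333333333,0.66666666667],[0.66666666667,0.66666666667],[0.66666666667,1],[0.33333333333,1],[0.33333333333,0.66666666667]]]}},{"type":"Feature","properties":{"id":"A009"},"geometry":{"type":"Polygon","coordinates":[[[0.66666666667,0.66666666667],[1,0.66666666667],[1,1],[0.66666666667,1],[0.66666666667,0.66666666667]]]}}]}
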
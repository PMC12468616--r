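{
  "_comment": "Synthetic miniature annotation file in the MIDOG (COCO-like) layout, for reader tests. Not derived from any real dataset.",
  "images": [
    {"id": 1, "file_name": "001.tiff", "width": 7215, "height": 5412},
    {"id": 2, "file_name": "002.tiff", "width": 7215, "height": 5412}
  ],
  "categories": [
    {"id": 1, "name": "mitotic figure"},
    {"id": 2, "name": "non-mitotic figure"}
  ],
  "annotations": [
    {"id": 1, "image_id": 1, "category_id": 1, "bbox": [100, 200, 50, 50]},
    {"id": 2, "image_id": 1, "category_id": 2, "bbox": [500, 600, 50, 50]},
    {"id": 3, "image_id": 2, "category_id": 1, "bbox": [300, 400, 50, 50]}
  ]
}
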
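指揮中心
急性呼吸道感染
新型冠狀病毒
自主健康管理
新型病毒
潛伏期
纖維化
自主管理
家庭感染
冠狀病毒
醫師
醫生
醫院
病毒
疫情
口罩
負壓
抗疫
陽性
陰性
群聚
隔離
確診
武漢
譚德塞
李文亮
新冠
染疫
武肺
封城
肺炎
防疫
奎寧
感染
出門
專家
院士
強調
提醒
政府
台灣
大陸
中國
民眾
訊息
消息
轉發
分享
注意
嚴重
死亡
症狀
咳嗽
發燒
喉嚨
鹽水
喝水
洗手
建議
公共場所
元宵
端午節
衛福部
部長
陳時中
鍾南山
鐘南山
疾管署
健康
身體
藥物
特效藥
治療
治癒
後遺症
瘟疫
戰役
家人
重要
期間
關鍵
措施
蔬菜
運動
公車
捷運
夜市
市場
髮廊
健身房
首飾
錢幣
電話
消毒
溫水
隱形眼鏡
立法院
記者會
新聞
報導
闢謠
查核
假訊息
謠言
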